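#' @import methods
#' @importFrom stats plogis qlogis rnorm runif rbinom rpois rlnorm sd var cor
#'   cov vcov quantile pchisq pnorm qnorm chisq.test fisher.test wilcox.test
#'   glm binomial coef predict median setNames aggregate
#' @importFrom utils head write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib noduleTLR, .registration = TRUE
NULL

#' CT display window
#'
#' A linear Hounsfield-unit display window defined by its centre (`level`)
#' and total `width`; values below `level - width/2` map to 0 and values
#' above `level + width/2` map to 1.
#'
#' @slot level window centre in HU.
#' @slot width window width in HU; must be positive.
#' @export
setClass("WindowSpec", representation(level = "numeric", width = "numeric"),
         validity = function(object) {
           if (length(object@level) != 1L || length(object@width) != 1L)
             return("level and width must be scalars")
           if (!is.finite(object@level) || !is.finite(object@width))
             return("level and width must be finite")
           if (object@width <= 0) return("width must be positive")
           TRUE
         })

#' Set of nodule-centred CT patches
#'
#' Holds windowed, nodule-centred patches together with per-patient metadata.
#' Pixels are stored as one 2-D matrix per patch in `[0, 1]`; the model input
#' is the patch replicated across `channels` identical channels (see
#' [patchArray()]).
#'
#' @slot pixels list of H x W numeric matrices, all the same size, values in
#'   `[0, 1]`.
#' @slot pheno data.frame with one row per patch; must contain columns
#'   `patient_id`, `cohort`, `label` and `provenance`. `label` is 0 (LGN),
#'   1 (LAC) or `NA` (unknown).
#' @slot window the [WindowSpec-class] used to render the pixels.
#' @slot channels number of replicated channels (default 3).
#' @export
setClass("CtPatchSet",
         representation(pixels = "list", pheno = "data.frame",
                        window = "WindowSpec", channels = "integer"),
         validity = function(object) {
           px <- object@pixels
           if (length(px) != nrow(object@pheno))
             return("pheno rows must match number of patches")
           need <- c("patient_id", "cohort", "label", "provenance")
           miss <- setdiff(need, names(object@pheno))
           if (length(miss)) return(paste("pheno lacks columns:",
                                          paste(miss, collapse = ", ")))
           if (length(px)) {
             d <- dim(px[[1L]])
             for (m in px) {
               if (!is.matrix(m) || !identical(dim(m), d))
                 return("all patches must be matrices of identical size")
               rng <- range(m)
               if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 1)
                 return("pixel values must be finite and in [0, 1]")
             }
           }
           lab <- object@pheno$label
           if (!all(is.na(lab) | lab %in% c(0, 1) | lab >= 0))
             return("labels must be non-negative class codes or NA")
           if (object@channels < 1L) return("channels must be >= 1")
           TRUE
         })

#' Backbone network configuration
#'
#' Reference design for the convolutional backbone: a fixed `stemPool`-fold
#' average-pooling stem followed by six 3x3 stride-2 convolution stages.
#' Global-average-pooled stage outputs concatenate to
#' `sum(scaledChannels(cfg))` transfer-learning features; at the default
#' widths and `widthScale = 1` this is exactly 3904.
#'
#' @slot stageChannels integer vector of per-stage output channels at
#'   `widthScale = 1` (default `c(64, 128, 256, 512, 1024, 1920)`).
#' @slot inputSize input spatial size (default 224).
#' @slot stemPool average-pooling factor of the fixed stem (default 4).
#' @slot kernel,stride convolution kernel size and stride.
#' @slot widthScale multiplier applied to `stageChannels` for desk-scale
#'   training runs.
#' @slot nSourceClasses,nTargetClasses class counts of the two tasks.
#' @slot train list of training hyper-parameters (epochs, batch, lr, ...).
#' @export
setClass("NetworkConfig",
         representation(stageChannels = "integer", inputSize = "integer",
                        stemPool = "integer", kernel = "integer",
                        stride = "integer", widthScale = "numeric",
                        nSourceClasses = "integer", nTargetClasses = "integer",
                        train = "list"),
         validity = function(object) {
           if (any(object@stageChannels <= 0L)) return("stage channels must be positive")
           if (object@widthScale <= 0) return("widthScale must be positive")
           if (object@inputSize %% object@stemPool != 0L)
             return("inputSize must be divisible by stemPool")
           if (object@inputSize / object@stemPool < 2^length(object@stageChannels) / 2)
             return("input too small for the number of stages")
           TRUE
         })

#' Convolutional network weights
#'
#' Weight container for the backbone plus a linear classification head.
#' Each stage weight is a `(k*k*Cin) x Cout` matrix (rows ordered
#' ki-fastest, then kj, then input channel) with a bias vector.
#'
#' @slot config the [NetworkConfig-class] used to build the network.
#' @slot weights list of per-stage `list(W, b)`.
#' @slot head `list(W, b)` of the linear classifier on the pooled last stage.
#' @slot nClasses number of output classes.
#' @slot cin number of input channels.
#' @slot seed integer seed the weights were initialised from.
#' @export
setClass("ConvNet",
         representation(config = "NetworkConfig", weights = "list",
                        head = "list", nClasses = "integer", cin = "integer",
                        seed = "integer"))

#' Meta-selection state for adaptive transfer
#'
#' State of the two meta-networks of the source-feature-selection constraint:
#' meta-network A produces per-channel gates
#' `g = sigmoid(gateLogits + gateSlope * pooled source activation)` and
#' meta-network B is a per-channel affine matching map from target-stage to
#' source-stage feature space.
#'
#' @slot gateLogits,gateSlope per-stage numeric vectors of meta-network A
#'   parameters (all zero gives gates of exactly 0.5).
#' @slot matchScale,matchShift per-stage numeric vectors of meta-network B.
#' @slot lambda constraint weight, `>= 0`.
#' @slot utilityRef reference utility level against which per-channel source
#'   usefulness is judged during the validation-driven gate update.
#' @export
setClass("MetaSelectionState",
         representation(gateLogits = "list", gateSlope = "list",
                        matchScale = "list", matchShift = "list",
                        lambda = "numeric", utilityRef = "numeric"),
         validity = function(object) {
           if (object@lambda < 0) return("lambda must be >= 0")
           ok <- vapply(c(object@gateLogits, object@gateSlope,
                          object@matchScale, object@matchShift),
                        function(v) all(is.finite(v)), logical(1L))
           if (!all(ok)) return("meta parameters must be finite")
           TRUE
         })

#' Sparse Bayesian ELM signature model
#'
#' Linear-kernel sparse Bayesian extreme learning machine: ARD Bayesian
#' logistic regression whose evidence-driven precision updates prune
#' irrelevant features; the surviving weights define the transfer learning
#' signature (TLS) score.
#'
#' @slot featureIds names of retained features.
#' @slot weights posterior-mode weights over retained features.
#' @slot intercept model intercept.
#' @slot alpha final ARD precisions of retained features.
#' @slot center,scale training-cohort standardisation constants (all
#'   screened features).
#' @slot screened names of the screened candidate features the model saw.
#' @slot converged,iterations ARD loop diagnostics.
#' @slot nullModel TRUE when every feature was pruned (intercept-only).
#' @export
setClass("SbelmModel",
         representation(featureIds = "character", weights = "numeric",
                        intercept = "numeric", alpha = "numeric",
                        center = "numeric", scale = "numeric",
                        screened = "character", converged = "logical",
                        iterations = "integer", nullModel = "logical"))

#' Transfer learning radiomics model (TLRM)
#'
#' Sparse-Bayes-LASSO fusion of clinical factors, subjective CT findings and
#' the TLS score into a single logistic risk model.
#'
#' @slot terms names of retained covariates.
#' @slot coefficients weights over retained covariates (standardised scale).
#' @slot intercept model intercept.
#' @slot center,scale standardisation constants over all candidates.
#' @slot candidates candidate covariates offered to the selector.
#' @slot priorScale Laplace prior rate used for the fit.
#' @slot evidence approximate log evidence at `priorScale`.
#' @export
setClass("TlrmModel",
         representation(terms = "character", coefficients = "numeric",
                        intercept = "numeric", center = "numeric",
                        scale = "numeric", candidates = "character",
                        priorScale = "numeric", evidence = "numeric"))

#' Clinical comparator model
#'
#' Multivariable logistic regression over gender, age, lobulated shape and
#' spiculated sign.
#'
#' @slot coefficients,se coefficient estimates and standard errors.
#' @slot terms covariate names (model-matrix columns).
#' @slot separation TRUE when quasi-separation forced the ridge fallback.
#' @slot fit the underlying fitted object.
#' @export
setClass("ClinicalModel",
         representation(coefficients = "numeric", se = "numeric",
                        terms = "character", separation = "logical",
                        fit = "ANY"))

#' Domain embedding for Wasserstein comparison
#'
#' Per-image feature vectors of one domain under a stated frozen extractor,
#' tagged with a fingerprint of that extractor so only like-embedded domains
#' are ever compared.
#'
#' @slot features n x d matrix of per-image embeddings.
#' @slot domain domain tag.
#' @slot fingerprint extractor fingerprint (hash of weights + stage).
#' @export
setClass("DomainEmbedding",
         representation(features = "matrix", domain = "character",
                        fingerprint = "character"),
         validity = function(object) {
           if (!nrow(object@features)) return("embedding is empty")
           if (!all(is.finite(object@features))) return("embedding has non-finite values")
           TRUE
         })
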