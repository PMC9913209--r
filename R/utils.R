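# internal helpers shared across modules

#' @importFrom withr with_seed
withSeed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# md5 of an arbitrary R object via a canonical serialisation (version 3,
# no header timestamps); used for run manifests and extractor fingerprints
objHash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 3L, compress = FALSE)
  unname(tools::md5sum(f))
}

stopData <- function(...) stop(errorCondition(paste0(...), class = c("tlrDataError", "error")))
stopParam <- function(...) stop(errorCondition(paste0(...), class = c("tlrParamError", "error")))
stopShape <- function(...) stop(errorCondition(paste0(...), class = c("tlrShapeError", "error")))
stopSchema <- function(...) stop(errorCondition(paste0(...), class = c("tlrSchemaError", "error")))

isBinaryLabels <- function(y) length(unique(y[!is.na(y)])) == 2L

# 0/1 labels from a factor/character/numeric label column (LAC = 1)
asLabel01 <- function(label) {
  if (is.numeric(label)) return(as.integer(label != 0))
  lev <- as.character(label)
  as.integer(lev %in% c("LAC", "1", "case", "positive"))
}
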