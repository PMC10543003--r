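# Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm rpois rmultinom cor median pt p.adjust phyper
#'   wilcox.test setNames runif complete.cases as.dist dist hclust sd var
#' @importFrom SummarizedExperiment assays<-
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

checkScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                              integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single non-missing number", call. = FALSE)
  if (x < lower || x > upper)
    stop("'", name, "' must be in [", lower, ", ", upper, "]", call. = FALSE)
  if (integer && x != as.integer(x))
    stop("'", name, "' must be a whole number", call. = FALSE)
  invisible(x)
}

# The 20 standard amino-acid one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
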