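# Internal helpers: argument checking and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(name, " must be a single finite number")
  if (integer && x != round(x)) stop_(name, " must be an integer")
  if (x < lower || x > upper)
    stop_(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

#' Derive a child seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline derives its own seed from the master
#' seed, a stage name, and (optionally) a subject index, so that results are
#' reproducible independently of execution order. The derivation is a small
#' deterministic integer hash kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param ... further labels (strings or integers) identifying the stage,
#'   subject, run, etc.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  check_number(seed, "seed", integer = TRUE)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab)
    for (cc in codes) {
      # 31-bit multiplicative hash; doubles hold intermediates exactly
      h <- (h * 69069 + as.double(cc) + 1) %% m
    }
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# canonical relabeling: module labels renumbered 1..K in order of first
# appearance (column-major over the L x N label matrix)
canonical_labels <- function(labels) {
  v <- as.vector(t(labels))
  u <- unique(v)
  m <- match(v, u)
  matrix(m, nrow = nrow(labels), byrow = TRUE,
         dimnames = dimnames(labels))
}

same_partition <- function(a, b) {
  identical(dim(a), dim(b)) &&
    identical(canonical_labels(a), canonical_labels(b))
}
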