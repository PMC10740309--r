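#' @keywords internal
"_PACKAGE"

# Canonical 18-region SENT_CORE labels, in atlas table order.
SENT_CORE_LABELS <- c(
  "prec4", "F1_2", "f2_2", "F3t", "F3O1", "INSa2", "INSa3", "T1_4",
  "T2_3", "T2_4", "STS1", "STS2", "STS3", "STS4", "SMG7", "AG2",
  "SMA2", "SMA3"
)

#' SENT_CORE region labels
#'
#' The 18 left-hemisphere sentence-processing regions of the SENSAAS atlas,
#' in the canonical table order used throughout the package.
#'
#' @return Character vector of length 18.
#' @export
sent_core_labels <- function() SENT_CORE_LABELS

#' Derive reproducible child seeds from a master seed
#'
#' Stream-splitting scheme used by every stochastic stage: the master seed
#' initialises one `sample.int()` draw of named 31-bit child seeds, so each
#' stage (and each ROI within a battery) owns an independent, re-derivable
#' stream. Re-running a single stage in isolation with its derived seed
#' reproduces its numbers exactly.
#'
#' @param master_seed Single integer.
#' @param names Character vector naming the streams to derive.
#' @return Named integer vector of seeds, one per name.
#' @export
derive_seeds <- function(master_seed, names) {
  stopifnot(is.character(names), length(names) >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}

# run expr under a local RNG state seeded with `seed`; restores caller RNG
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_numeric_vec <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) stop_field(name, "must be numeric")
  if (finite && any(!is.finite(x))) stop_field(name, "contains non-finite values")
  if (positive && any(x <= 0)) stop_field(name, "must be strictly positive")
  invisible(x)
}
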