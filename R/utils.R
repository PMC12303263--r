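#' @keywords internal
"_PACKAGE"

# Canonical labels used throughout: recording conditions and trait scales.
# Social traits are ordered (likeable, hostile, intelligent); this order
# fixes the RSM cell layout everywhere.
VM_CONDITIONS <- c("neutral", "large", "hostile", "likeable", "intelligent")
VM_SOCIAL_TRAITS <- c("likeable", "hostile", "intelligent")

#' Derive a stream-specific 32-bit seed from a global seed
#'
#' All stochastic stages draw their seed through this function so that a
#' single integer reproduces every fixture, while distinct stages
#' (ratings, questionnaires, volumes, Monte-Carlo nulls) get decoupled
#' streams.
#'
#' @param seed integer global seed.
#' @param stream character tag naming the consumer (e.g. `"ratings"`).
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 10007) %% 2147483647)
}

vm_stop <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "voicemod_error")))
}

#' Normalize condition/scale labels (casefold, trim)
#' @param x character vector of labels.
#' @param allowed allowed canonical labels, or NULL to skip the check.
#' @return Canonicalized character vector.
#' @keywords internal
vm_normalize_label <- function(x, allowed = NULL) {
  out <- tolower(trimws(as.character(x)))
  if (!is.null(allowed)) {
    bad <- setdiff(unique(out), allowed)
    if (length(bad) > 0) {
      vm_stop("unknown label(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(allowed, collapse = ", "),
              class = "voicemod_validation_error")
    }
  }
  out
}

# Evaluate code under a local RNG seed, restoring the caller's RNG state.
vm_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Pearson correlation written out from the textbook formula; kept separate
# from stats::cor so degenerate vectors fail loudly with context.
vm_pearson <- function(x, y, what = "vector") {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) {
    vm_stop("zero-variance %s: Pearson correlation undefined", what,
            class = "voicemod_degenerate_error")
  }
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}
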