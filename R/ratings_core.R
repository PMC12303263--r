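#' Per-speaker trait-change index (Delta-trait)
#'
#' Mean change, over listeners, in naive ratings of a trait-modulated
#' recording relative to the same speaker's neutral recording, on the
#' trait's own scale. Positive values mean the modulation moved listener
#' percepts in the intended direction, in Likert points.
#'
#' Listeners contributing only one member of the (modulated, neutral) pair
#' are excluded listwise; the number dropped is reported via the
#' `"n_excluded"` attribute and a message.
#'
#' @param records ratings data.frame with columns `listener_id`,
#'   `speaker_id`, `condition`, `scale`, `rating` (see [read_ratings()]).
#' @param speaker_id speaker to evaluate.
#' @param trait one of `"likeable"`, `"hostile"`, `"intelligent"`.
#' @return Numeric scalar: mean paired difference in Likert points, with
#'   attributes `n_pairs` and `n_excluded`.
#' @export
#' @examples
#' r <- data.frame(
#'   listener_id = rep(1:2, each = 2), speaker_id = "s1",
#'   condition = rep(c("likeable", "neutral"), 2),
#'   scale = "likeable", rating = c(5, 3, 6, 2))
#' delta_trait(r, "s1", "likeable")  # (2 + 4) / 2 = 3
delta_trait <- function(records, speaker_id, trait) {
  trait <- vm_normalize_label(trait, VM_SOCIAL_TRAITS)
  rec <- records[records$speaker_id == speaker_id & records$scale == trait, ]
  mod <- rec[rec$condition == trait, c("listener_id", "rating")]
  neu <- rec[rec$condition == "neutral", c("listener_id", "rating")]
  m <- merge(mod, neu, by = "listener_id", suffixes = c("_mod", "_neu"))
  n_excluded <- length(unique(c(mod$listener_id, neu$listener_id))) - nrow(m)
  if (nrow(m) == 0) {
    vm_stop("speaker %s, trait %s: no listener rated both the modulated and neutral recording",
            speaker_id, trait, class = "voicemod_insufficient_data")
  }
  if (n_excluded > 0) {
    message(sprintf("delta_trait(%s, %s): excluded %d listener(s) with incomplete pairs",
                    speaker_id, trait, n_excluded))
  }
  structure(mean(m$rating_mod - m$rating_neu),
            n_pairs = nrow(m), n_excluded = n_excluded)
}

#' Theoretical maximal-discrimination RSM
#'
#' The reference representational similarity matrix under perfectly
#' specific trait expression: likeable and hostile percepts anti-correlated
#' (r = -1), intelligence uncorrelated with both (r = 0).
#'
#' @return 3x3 correlation matrix over (likeable, hostile, intelligent).
#' @export
theoretical_rsm <- function() {
  m <- diag(3)
  dimnames(m) <- list(VM_SOCIAL_TRAITS, VM_SOCIAL_TRAITS)
  m["likeable", "hostile"] <- m["hostile", "likeable"] <- -1
  m
}

vm_check_rsm <- function(m, name = "rsm", tol = 1e-9) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L))) {
    vm_stop("%s must be a 3x3 matrix", name, class = "voicemod_validation_error")
  }
  if (max(abs(m - t(m))) > tol) {
    vm_stop("%s is asymmetric beyond tolerance %g", name, tol,
            class = "voicemod_validation_error")
  }
  if (max(abs(diag(m) - 1)) > tol) {
    vm_stop("%s diagonal must be 1", name, class = "voicemod_validation_error")
  }
  if (max(abs(m)) > 1 + tol) {
    vm_stop("%s has |cell| > 1", name, class = "voicemod_validation_error")
  }
  invisible(m)
}

#' Build a speaker's rating RSM
#'
#' Pairwise Pearson correlations between trait-scale rating vectors for one
#' speaker. In the default `"scalewise"` mode, the vector for scale *i*
#' stacks, over listeners and the three social-trait recordings (likeable,
#' hostile, intelligent conditions), the ratings given on scale *i*; with L
#' complete listeners each vector has length 3L. The alternative
#' `"profile"` mode correlates per-listener-mean rating profiles over the
#' three recordings (vectors of length 3). Neutral and large-body-size
#' recordings never enter the RSM.
#'
#' Only listeners who rated all three social recordings on all three scales
#' contribute (listwise completion); a message reports any dropped.
#'
#' @inheritParams delta_trait
#' @param mode `"scalewise"` (default) or `"profile"`.
#' @return 3x3 correlation matrix over (likeable, hostile, intelligent),
#'   unit diagonal, symmetric.
#' @export
build_rsm <- function(records, speaker_id, mode = c("scalewise", "profile")) {
  mode <- match.arg(mode)
  rec <- records[records$speaker_id == speaker_id &
                   records$condition %in% VM_SOCIAL_TRAITS &
                   records$scale %in% VM_SOCIAL_TRAITS, ]
  if (nrow(rec) == 0) {
    vm_stop("speaker %s: no social-trait ratings found", speaker_id,
            class = "voicemod_insufficient_data")
  }
  # complete listeners: all 3 conditions x 3 scales present
  tab <- table(rec$listener_id)
  complete <- names(tab)[tab == 9L]
  dropped <- setdiff(names(tab), complete)
  if (length(complete) < 2) {
    vm_stop("speaker %s: %d complete listener(s); need >= 2 for correlations",
            speaker_id, length(complete), class = "voicemod_insufficient_data")
  }
  if (length(dropped) > 0) {
    message(sprintf("build_rsm(%s): dropped %d incomplete listener(s)",
                    speaker_id, length(dropped)))
  }
  rec <- rec[rec$listener_id %in% complete, ]
  # fixed (listener, condition) ordering so scale vectors align
  rec <- rec[order(match(rec$listener_id, complete),
                   match(rec$condition, VM_SOCIAL_TRAITS)), ]
  vecs <- lapply(VM_SOCIAL_TRAITS, function(sc) {
    v <- rec$rating[rec$scale == sc]
    if (mode == "profile") {
      # mean over listeners per recording -> 3-vector profile
      v <- tapply(v, rec$condition[rec$scale == sc], mean)[VM_SOCIAL_TRAITS]
    }
    as.numeric(v)
  })
  names(vecs) <- VM_SOCIAL_TRAITS
  m <- diag(3)
  dimnames(m) <- list(VM_SOCIAL_TRAITS, VM_SOCIAL_TRAITS)
  for (i in 1:2) for (j in (i + 1):3) {
    for (k in c(i, j)) {
      if (stats::sd(vecs[[k]]) == 0) {
        vm_stop("speaker %s: zero variance in '%s' scale ratings; RSM cell undefined",
                speaker_id, VM_SOCIAL_TRAITS[k],
                class = "voicemod_degenerate_error")
      }
    }
    m[i, j] <- m[j, i] <- vm_pearson(vecs[[i]], vecs[[j]])
  }
  m
}

#' Social voice modulation index (Euclidean distance to theoretical RSM)
#'
#' Euclidean distance between a speaker's RSM and the theoretical
#' maximal-discrimination matrix, taken over the three unique off-diagonal
#' cells. Range 0 (perfect specificity) to sqrt(6) ~ 2.45; smaller values
#' denote higher specificity of the evoked trait percepts.
#'
#' @param rsm speaker 3x3 correlation matrix.
#' @param theoretical reference matrix; defaults to [theoretical_rsm()].
#' @return Nonnegative scalar in `[0, sqrt(6)]`.
#' @export
#' @examples
#' modulation_index(theoretical_rsm())                    # 0
#' worst <- matrix(1, 3, 3)
#' modulation_index(worst)                                # sqrt(6) = 2.449...
modulation_index <- function(rsm, theoretical = theoretical_rsm()) {
  vm_check_rsm(rsm, "rsm")
  vm_check_rsm(theoretical, "theoretical")
  idx <- cbind(c(1, 1, 2), c(2, 3, 3))  # unique off-diagonal cells
  sqrt(sum((rsm[idx] - theoretical[idx])^2))
}

#' One-sample t-test on per-speaker Delta-trait indices
#'
#' Tests whether the mean trait change differs from zero. With n speakers
#' the statistic has n - 1 degrees of freedom.
#'
#' @param deltas numeric vector of per-speaker Delta values.
#' @param tail `"two.sided"` (default) or `"greater"`.
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `n`. Zero variance in
#'   `deltas` yields an infinite t flagged via `degenerate = TRUE`.
#' @export
delta_ttest <- function(deltas, tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  n <- length(deltas)
  if (n < 2) vm_stop("need >= 2 values for a t-test", class = "voicemod_validation_error")
  m <- mean(deltas); s <- stats::sd(deltas)
  if (s == 0) {
    return(list(t = sign(m) * Inf, df = n - 1L, p = if (m == 0) 1 else 0,
                mean = m, sd = s, n = n, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  p <- switch(tail,
              two.sided = 2 * stats::pt(-abs(t), df = n - 1),
              greater = stats::pt(t, df = n - 1, lower.tail = FALSE))
  list(t = t, df = n - 1L, p = p, mean = m, sd = s, n = n, degenerate = FALSE)
}

#' Per-speaker performance table
#'
#' Convenience wrapper running [delta_trait()], [build_rsm()] and
#' [modulation_index()] for every speaker in a ratings table. Also reports
#' the mean likeability rating of each speaker's neutral recording (used by
#' the neutral-voice control analysis).
#'
#' @inheritParams build_rsm
#' @return data.frame with one row per speaker: `speaker_id`,
#'   `delta_hostility`, `delta_likeability`, `delta_intelligence`, `ed`,
#'   `neutral_likeability`.
#' @export
compute_performance <- function(records, mode = c("scalewise", "profile")) {
  mode <- match.arg(mode)
  speakers <- sort(unique(records$speaker_id))
  theo <- theoretical_rsm()
  rows <- lapply(speakers, function(sp) {
    neu <- records$rating[records$speaker_id == sp &
                            records$condition == "neutral" &
                            records$scale == "likeable"]
    data.frame(
      speaker_id = sp,
      delta_hostility = as.numeric(delta_trait(records, sp, "hostile")),
      delta_likeability = as.numeric(delta_trait(records, sp, "likeable")),
      delta_intelligence = as.numeric(delta_trait(records, sp, "intelligent")),
      ed = modulation_index(build_rsm(records, sp, mode = mode), theo),
      neutral_likeability = if (length(neu)) mean(neu) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format RSM table for a set of speakers
#'
#' @inheritParams build_rsm
#' @return data.frame `speaker_id`, `pair` (e.g. `"likeable:hostile"`), `r`.
#' @export
rsm_table <- function(records, mode = c("scalewise", "profile")) {
  mode <- match.arg(mode)
  speakers <- sort(unique(records$speaker_id))
  pairs <- cbind(c(1, 1, 2), c(2, 3, 3))
  do.call(rbind, lapply(speakers, function(sp) {
    m <- build_rsm(records, sp, mode = mode)
    data.frame(
      speaker_id = sp,
      pair = paste(VM_SOCIAL_TRAITS[pairs[, 1]], VM_SOCIAL_TRAITS[pairs[, 2]],
                   sep = ":"),
      r = m[pairs], stringsAsFactors = FALSE)
  }))
}
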