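#' Default instrument keymap
#'
#' Item-to-subscale assignments and reverse-keying flags for the QCAE
#' (31 items, 4-point responses; 19 cognitive + 12 affective) and the SD3
#' (27 items, 5-point responses; 9 items each for Machiavellianism,
#' psychopathy and narcissism). The published instruments do not travel
#' with this package, so the shipped map is a straight-keyed synthetic
#' stand-in (no reverse-keyed items): it preserves item counts, response
#' ranges and the printed sum-score ranges, not the original item order or
#' keying. Supply your own keymap file for a faithful scoring run.
#'
#' @param path optional path to a CSV with columns `instrument`
#'   (`"qcae"`/`"sd3"`), `item` (1-based within instrument), `subscale`,
#'   `reverse` (logical).
#' @return data.frame keymap.
#' @export
default_keymap <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "keymap_qcae_sd3.csv", package = "voicemod")
  }
  km <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instrument", "item", "subscale", "reverse")
  if (!all(need %in% names(km))) {
    vm_stop("keymap must have columns %s", paste(need, collapse = ", "),
            class = "voicemod_validation_error")
  }
  km$reverse <- as.logical(km$reverse)
  km
}

# instrument metadata: items, response range, subscales and their sizes
vm_instruments <- list(
  qcae = list(n_items = 31L, lo = 1L, hi = 4L,
              subscales = c(cognitive_empathy = 19L, affective_empathy = 12L)),
  sd3 = list(n_items = 27L, lo = 1L, hi = 5L,
             subscales = c(machiavellianism = 9L, psychopathy = 9L,
                           narcissism = 9L))
)

#' Apply reverse keying to a response vector
#'
#' Reverse-keyed items map response r to (lo + hi - r); applying the map
#' twice is the identity.
#'
#' @param responses integer responses, one per item (in item order).
#' @param reverse logical vector, same length.
#' @param lo,hi response bounds.
#' @return Keyed responses.
#' @export
apply_keying <- function(responses, reverse, lo, hi) {
  ifelse(reverse, lo + hi - responses, responses)
}

vm_validate_items <- function(responses, instrument, keymap) {
  meta <- vm_instruments[[instrument]]
  km <- keymap[keymap$instrument == instrument, ]
  km <- km[order(km$item), ]
  problems <- character(0)
  if (nrow(km) != meta$n_items || !identical(km$item, seq_len(meta$n_items))) {
    problems <- c(problems, sprintf("keymap lists %d %s items, expected %d (1..%d)",
                                    nrow(km), instrument, meta$n_items, meta$n_items))
  }
  if (length(responses) != meta$n_items) {
    problems <- c(problems, sprintf("%d responses supplied, expected %d",
                                    length(responses), meta$n_items))
  }
  bad <- which(is.na(responses) | responses < meta$lo | responses > meta$hi |
                 responses != round(responses))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf("item %d response %s outside {%d..%d}",
                                    bad, responses[bad], meta$lo, meta$hi))
  }
  cnt <- table(factor(km$subscale, levels = names(meta$subscales)))
  off <- which(as.integer(cnt) != as.integer(meta$subscales))
  if (length(off) > 0) {
    problems <- c(problems, sprintf("subscale %s has %d items, expected %d",
                                    names(meta$subscales)[off],
                                    as.integer(cnt)[off],
                                    as.integer(meta$subscales)[off]))
  }
  if (length(problems) > 0) {
    vm_stop("%s scoring: %s", instrument, paste(problems, collapse = "; "),
            class = "voicemod_validation_error")
  }
  km
}

vm_score_instrument <- function(responses, instrument, keymap, keep) {
  meta <- vm_instruments[[instrument]]
  km <- vm_validate_items(responses, instrument, keymap)
  keyed <- apply_keying(responses, km$reverse, meta$lo, meta$hi)
  out <- vapply(keep, function(sc) sum(keyed[km$subscale == sc]), numeric(1))
  names(out) <- keep
  out
}

#' Score the QCAE into cognitive and affective empathy sums
#'
#' @param responses 31 integer responses in 1..4, in keymap item order.
#' @param keymap see [default_keymap()].
#' @return Named numeric: `cognitive_empathy` (19-76),
#'   `affective_empathy` (12-48).
#' @export
score_qcae <- function(responses, keymap = default_keymap()) {
  vm_score_instrument(responses, "qcae", keymap,
                      c("cognitive_empathy", "affective_empathy"))
}

#' Score the SD3 into Machiavellianism and psychopathy sums
#'
#' Narcissism items are validated but not returned (the downstream
#' analyses use only Machiavellianism and psychopathy).
#'
#' @param responses 27 integer responses in 1..5, in keymap item order.
#' @inheritParams score_qcae
#' @return Named numeric: `machiavellianism` (9-45), `psychopathy` (9-45).
#' @export
score_sd3 <- function(responses, keymap = default_keymap()) {
  vm_score_instrument(responses, "sd3", keymap,
                      c("machiavellianism", "psychopathy"))
}

#' Cronbach's alpha
#'
#' Internal consistency of a respondent-by-item score matrix:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of total score).
#'
#' @param item_matrix numeric matrix, n respondents x k items (k >= 2),
#'   no missing values.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (anyNA(m)) vm_stop("missing values not allowed", class = "voicemod_validation_error")
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2) {
    vm_stop("need >= 2 items and >= 2 respondents", class = "voicemod_validation_error")
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    vm_stop("total score has zero variance; alpha undefined",
            class = "voicemod_degenerate_error")
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Score a long-format questionnaire table into reactivity profiles
#'
#' @param items data.frame with columns `speaker_id`, `instrument`
#'   (`"qcae"`/`"sd3"`), `item`, `response`.
#' @param speakers data.frame with `speaker_id`, `age`, `sex`
#'   (`"female"`/`"male"`).
#' @inheritParams score_qcae
#' @return data.frame, one row per speaker: the four index sum scores plus
#'   `age` and `sex`.
#' @export
score_profiles <- function(items, speakers, keymap = default_keymap()) {
  ids <- sort(unique(items$speaker_id))
  rows <- lapply(ids, function(sp) {
    it <- items[items$speaker_id == sp, ]
    grab <- function(instr) {
      sub <- it[it$instrument == instr, ]
      sub$response[order(sub$item)]
    }
    q <- score_qcae(grab("qcae"), keymap)
    s <- score_sd3(grab("sd3"), keymap)
    data.frame(speaker_id = sp,
               cognitive_empathy = q[["cognitive_empathy"]],
               affective_empathy = q[["affective_empathy"]],
               machiavellianism = s[["machiavellianism"]],
               psychopathy = s[["psychopathy"]],
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  sp <- speakers[, c("speaker_id", "age", "sex")]
  sp$sex <- vm_normalize_label(sp$sex, c("female", "male"))
  if (any(sp$age <= 0)) {
    vm_stop("age must be positive", class = "voicemod_validation_error")
  }
  out <- merge(prof, sp, by = "speaker_id")
  if (nrow(out) != length(ids)) {
    vm_stop("speaker table is missing %d scored speaker(s)",
            length(ids) - nrow(out), class = "voicemod_validation_error")
  }
  out
}
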