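#' Stimulus set geometry and luminances
#'
#' The stimulus is a bright figurine shown at one of five physical sizes,
#' spaced proportionally around a base height, inside an illusory 3D
#' corridor. Heights are derived as `base_height_deg * (1 + size_deltas)`.
#'
#' @param base_height_deg Height of the reference (middle) figurine in
#'   degrees of visual angle. Default 7.8.
#' @param size_deltas Ordered proportional offsets defining the five sizes.
#' @param luminance_figurine_cd_m2,luminance_green_cd_m2,luminance_red_cd_m2
#'   Display luminances in cd/m^2 (figurine against the equiluminant
#'   red/green corridor background).
#' @return An object of class `stimulus_set`.
#' @export
#' @examples
#' stimulus_heights(stimulus_set())
stimulus_set <- function(base_height_deg = 7.8,
                         size_deltas = c(-0.20, -0.10, 0, 0.10, 0.20),
                         luminance_figurine_cd_m2 = 55,
                         luminance_green_cd_m2 = 1.7,
                         luminance_red_cd_m2 = 2.0) {
  if (!is.numeric(base_height_deg) || length(base_height_deg) != 1L ||
      !is.finite(base_height_deg) || base_height_deg <= 0) {
    stop("`base_height_deg` must be a single positive number", call. = FALSE)
  }
  if (length(size_deltas) != 5L || is.unsorted(size_deltas, strictly = TRUE)) {
    stop("`size_deltas` must be 5 strictly increasing offsets", call. = FALSE)
  }
  structure(
    list(base_height_deg = base_height_deg,
         size_deltas = as.numeric(size_deltas),
         heights_deg = base_height_deg * (1 + as.numeric(size_deltas)),
         luminance_figurine_cd_m2 = luminance_figurine_cd_m2,
         luminance_green_cd_m2 = luminance_green_cd_m2,
         luminance_red_cd_m2 = luminance_red_cd_m2),
    class = "stimulus_set"
  )
}

#' Physical figurine heights in degrees of visual angle
#'
#' @param set A [stimulus_set()].
#' @return Numeric vector of 5 strictly increasing heights (degrees),
#'   ordered by size level 1..5.
#' @export
stimulus_heights <- function(set = stimulus_set()) {
  stopifnot(inherits(set, "stimulus_set"))
  set$heights_deg
}

#' Build a balanced randomized trial list
#'
#' A session comprises 100 trials: 5 figurine sizes x 2 corridor locations
#' (near/far) x 10 repetitions, administered in two blocks of 50. Each block
#' is constrained to contain 5 repetitions of each of the 10 cells, shuffled
#' within block, so both blocks are balanced mini-designs.
#'
#' @param seed Integer seed; the same seed reproduces the same ordering.
#' @return A data.frame with one row per trial and columns `block` (1-2),
#'   `trial` (1-50 within block), `size_level` (1-5), `location`
#'   ("near"/"far") and `repetition` (1-10 within cell, in order of
#'   occurrence).
#' @export
build_trial_list <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  cells <- expand.grid(size_level = 1:5,
                       location = c("near", "far"),
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  rng <- local_rng(seed)
  blocks <- lapply(1:2, function(b) {
    blk <- cells[rep(seq_len(nrow(cells)), each = 5L), ]
    blk <- blk[sample.int(nrow(blk)), ]
    blk$block <- b
    blk$trial <- seq_len(nrow(blk))
    blk
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  # label repetition 1..10 in order of occurrence within each cell
  key <- paste(out$size_level, out$location)
  out$repetition <- stats::ave(seq_along(key), key, FUN = seq_along)
  out[, c("block", "trial", "size_level", "location", "repetition")]
}

#' Score the Autism-Spectrum Quotient questionnaire
#'
#' Binary scoring of the 50-item AQ: an item scores 1 when the response is on
#' the pole characteristic of autistic traits (collapsing "slightly" and
#' "strongly"), 0 otherwise. Total ranges 0-50; scores of 32 or more flag
#' that a clinical assessment is recommended.
#'
#' @param responses Character vector of exactly 50 responses, each one of
#'   `"strongly_agree"`, `"slightly_agree"`, `"slightly_disagree"`,
#'   `"strongly_disagree"`. Missing responses are an error (no imputation).
#' @param scoring_key Logical (or 0/1) vector of length 50: `TRUE` where the
#'   *agree* pole is the trait-characteristic one for that item. The key is
#'   not bundled with the package and must be supplied.
#' @return An object of class `aq_score`: list with integer `score` and
#'   logical `clinical_flag` (`score >= 32`).
#' @export
score_aq <- function(responses, scoring_key) {
  levs <- c("strongly_agree", "slightly_agree",
            "slightly_disagree", "strongly_disagree")
  if (length(responses) != 50L) {
    stop("AQ requires exactly 50 responses, got ", length(responses),
         call. = FALSE)
  }
  if (length(scoring_key) != 50L) {
    stop("AQ scoring key must have exactly 50 entries", call. = FALSE)
  }
  if (anyNA(responses) || !all(responses %in% levs)) {
    bad <- which(is.na(responses) | !(responses %in% levs))
    stop("invalid or missing AQ response at item(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- as.logical(scoring_key)
  if (anyNA(key)) stop("AQ scoring key contains missing entries", call. = FALSE)
  agreed <- responses %in% c("strongly_agree", "slightly_agree")
  aq_score(sum(agreed == key))
}

#' Construct an AQ score object directly
#'
#' Used when item-level responses are unavailable and only the total score is
#' known (e.g. precomputed scores, or the synthetic generator which emits
#' binary item scores directly).
#'
#' @param score Integer total in 0..50.
#' @return An `aq_score` object.
#' @export
aq_score <- function(score) {
  score <- as.integer(score)
  stopifnot(length(score) == 1L, !is.na(score), score >= 0L, score <= 50L)
  structure(list(score = score, clinical_flag = score >= 32L),
            class = "aq_score")
}

#' @export
print.aq_score <- function(x, ...) {
  cat(sprintf("AQ score: %d (clinical cut-off %sreached)\n", x$score,
              if (x$clinical_flag) "" else "not "))
  invisible(x)
}

#' Read AQ responses and score them
#'
#' Responses CSV needs columns `participant_id`, `item` (1-50), `response`
#' (1-4 Likert coding: 1 = strongly agree .. 4 = strongly disagree). The key
#' CSV needs columns `item`, `agree_is_characteristic` (0/1).
#'
#' @param responses_path,key_path CSV file paths.
#' @return data.frame with `participant_id`, `aq`, `clinical_flag`.
#' @export
read_aq_responses <- function(responses_path, key_path) {
  resp <- utils::read.csv(responses_path, comment.char = "#")
  key <- utils::read.csv(key_path, comment.char = "#")
  need <- c("participant_id", "item", "response")
  if (!all(need %in% names(resp))) {
    stop("AQ responses file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("item", "agree_is_characteristic") %in% names(key))) {
    stop("AQ key file must have columns item, agree_is_characteristic",
         call. = FALSE)
  }
  key <- key[order(key$item), ]
  levs <- c("strongly_agree", "slightly_agree",
            "slightly_disagree", "strongly_disagree")
  out <- lapply(split(resp, resp$participant_id), function(d) {
    d <- d[order(d$item), ]
    if (!identical(as.integer(d$item), 1:50)) {
      stop("participant ", d$participant_id[1],
           ": AQ items must be exactly 1..50", call. = FALSE)
    }
    s <- score_aq(levs[d$response], key$agree_is_characteristic)
    data.frame(participant_id = d$participant_id[1],
               aq = s$score, clinical_flag = s$clinical_flag)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
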