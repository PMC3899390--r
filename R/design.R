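#' Build one randomised block of trials
#'
#' A block is a uniformly random permutation of 5 replicates of each of
#' the 10 cells of the 2 (square size) x 5 (treatment) factorial: 50
#' trials.
#'
#' @param block_no Block number (stored on each trial).
#' @param seed Optional integer seed.
#' @return Data frame with columns `block`, `index_in_block`, `treatment`,
#'   `square_size`, `practice` (always `FALSE`).
#' @export
build_block <- function(block_no, seed = NULL) {
  cells <- expand.grid(treatment = TREATMENTS, square_size = SIZES,
                       stringsAsFactors = FALSE)
  trials <- cells[rep(seq_len(nrow(cells)), each = 5L), ]
  with_seed(seed, {
    trials <- trials[sample.int(nrow(trials)), ]
  })
  rownames(trials) <- NULL
  data.frame(block = as.integer(block_no),
             index_in_block = seq_len(nrow(trials)),
             treatment = as_treatment(trials$treatment),
             square_size = as_size(trials$square_size),
             practice = FALSE)
}

#' Build a full session plan for one subject
#'
#' A session is 10 practice trials followed by 4 blocks of 50 main
#' trials, giving 200 main trials with every treatment x size cell seen
#' exactly 20 times. The stated practice composition ("two replicates of
#' each treatment combination" in 10 trials) cannot hold for 10 cells;
#' here practice contains two replicates of each of the five treatments
#' with the square size of each practice trial drawn at random, shuffled.
#' Per-trial scene seeds are spawned from the master seed by a
#' counter-based mix, so sessions are reproducible while scenes stay
#' independent across trials and subjects.
#'
#' @param subject_id Subject identifier (stored on each trial).
#' @param master_seed Integer master seed for the session.
#' @param n_blocks Number of main blocks (default 4; reduce for small
#'   simulation studies).
#' @return Object of class `camo_session`: data frame of trials (practice
#'   first) with columns `subject`, `block`, `trial`, `treatment`,
#'   `square_size`, `practice`, `scene_seed`, plus attribute
#'   `master_seed`.
#' @examples
#' plan <- build_session("S01", master_seed = 11)
#' table(plan$treatment[!plan$practice], plan$square_size[!plan$practice])
#' @export
build_session <- function(subject_id, master_seed, n_blocks = 4L) {
  stopifnot(n_blocks >= 1)
  practice <- with_seed(derive_seed(master_seed, 0L), {
    p <- data.frame(block = 0L, index_in_block = seq_len(10L),
                    treatment = as_treatment(rep(TREATMENTS, each = 2L)),
                    square_size = as_size(sample(SIZES, 10L, replace = TRUE)),
                    practice = TRUE)
    p[sample.int(10L), ]
  })
  practice$index_in_block <- seq_len(10L)
  blocks <- lapply(seq_len(n_blocks), function(b)
    build_block(b, seed = derive_seed(master_seed, b)))
  plan <- rbind(practice, do.call(rbind, blocks))
  rownames(plan) <- NULL
  plan <- data.frame(subject = subject_id, plan,
                     trial = seq_len(nrow(plan)))
  plan$scene_seed <- vapply(plan$trial, function(k)
    derive_seed(master_seed, 1000L + k), integer(1))
  plan <- plan[c("subject", "block", "trial", "treatment", "square_size",
                 "practice", "scene_seed")]
  structure(plan, class = c("camo_session", "data.frame"),
            master_seed = master_seed)
}
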