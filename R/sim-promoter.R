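#' Simulate a promoter sequence with motifs planted at TSS-relative positions
#'
#' Draws a random background of the requested GC content and substitutes each
#' planted subsequence at its signed TSS-relative position (the position names
#' the 5'-most plus-strand base of the element; minus-strand plantings are
#' reverse-complemented before substitution). Optionally the background is
#' resampled until it carries no off-target hits for a set of motifs, so that
#' a subsequent scan finds exactly the planted elements.
#'
#' @param length Total promoter length (bases).
#' @param tss_index 1-based index of the TSS base within the sequence.
#' @param planted A data frame with columns `name`, `sequence`,
#'   `tss_position` (signed, nonzero) and `strand` (`"+"`/`"-"`), or `NULL`
#'   for pure background.
#' @param gc_content Background GC fraction.
#' @param avoid_motifs Optional named list of [consensus_motif()] objects; the
#'   assembled sequence is rejected and the background redrawn (plantings
#'   kept) until scanning each motif at its `max_mismatch` on both strands
#'   yields hits only at the planted positions.
#' @param seed Integer seed.
#' @param max_tries Resampling cap for `avoid_motifs`.
#' @return A list with `sequence` (character string), `tss_index` and
#'   `truth` (a [new_sim_truth()] with a `planted_motifs` tibble).
#' @examples
#' sim <- simulate_promoter(
#'   length = 1000, tss_index = 801,
#'   planted = data.frame(name = "CArG", sequence = "ACTTTTATGG",
#'                        tss_position = 57, strand = "+"),
#'   seed = 1
#' )
#' substr(sim$sequence, 857, 866)
#' @export
simulate_promoter <- function(length,
                              tss_index,
                              planted = NULL,
                              gc_content = 0.5,
                              avoid_motifs = NULL,
                              seed = 1L,
                              max_tries = 200L) {
  stopifnot(length >= 1, tss_index >= 1, tss_index <= length)
  if (is.null(planted)) {
    planted <- tibble(name = character(), sequence = character(),
                      tss_position = integer(), strand = character())
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0) {
    stopifnot(all(c("name", "sequence", "tss_position", "strand") %in% names(planted)))
    if (any(planted$tss_position == 0)) {
      abort("Signed TSS positions are never 0.")
    }
    if (!all(planted$strand %in% c("+", "-"))) {
      abort("`strand` must be '+' or '-'.")
    }
  }

  offsets <- from_tss_coordinates(planted$tss_position, tss_index)
  ends <- offsets + nchar(planted$sequence) - 1L
  if (nrow(planted) > 0 && (any(offsets < 1) || any(ends > length))) {
    abort("A planted element falls outside the sequence.")
  }
  if (nrow(planted) > 1) {
    o <- order(offsets)
    if (any(offsets[o][-1] <= ends[o][-nrow(planted)])) {
      abort("Planted elements overlap.")
    }
  }

  base_prob <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                 G = gc_content / 2, T = (1 - gc_content) / 2)
  plant_strings <- ifelse(
    planted$strand == "+",
    toupper(planted$sequence),
    vapply(toupper(planted$sequence), reverse_complement, character(1))
  )
  planted_keys <- if (nrow(planted) > 0) {
    # a hit is "planted" if it starts at a planted offset (either strand)
    offsets
  } else {
    integer()
  }

  set.seed(seed)
  for (try in seq_len(max_tries)) {
    chars <- sample(names(base_prob), length, replace = TRUE, prob = base_prob)
    if (nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        chars[offsets[i]:ends[i]] <-
          strsplit(plant_strings[i], "", fixed = TRUE)[[1]]
      }
    }
    sequence <- paste(chars, collapse = "")
    if (is.null(avoid_motifs)) break
    spurious <- FALSE
    for (m in avoid_motifs) {
      hits <- scan_promoter(sequence, m, tss_index, strands = "both")
      extra <- setdiff(from_tss_coordinates(hits$tss_position, tss_index),
                       planted_keys)
      if (length(extra) > 0) {
        spurious <- TRUE
        break
      }
    }
    if (!spurious) break
    if (try == max_tries) {
      abort("Could not draw a background avoiding the given motifs.")
    }
  }

  truth <- new_sim_truth(
    kind = "promoter",
    planted_motifs = planted,
    tss_index = tss_index,
    gc_content = gc_content,
    seed = seed
  )
  list(sequence = sequence, tss_index = tss_index, truth = truth)
}
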