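# Degenerate consensus motifs and mismatch-tolerant promoter scanning.
#
# Pattern alphabet: A, C, G, T plus the IUPAC degeneracies W (A/T), R (A/G)
# and N (any). Sequence alphabet: A, C, G, T, N; an N in the sequence matches
# only an N in the pattern.

.seq_alphabet <- c("A", "C", "G", "T", "N")

# allowed[pattern_letter, sequence_letter]
.match_table <- local({
  pat <- c("A", "C", "G", "T", "W", "R", "N")
  m <- matrix(FALSE, length(pat), length(.seq_alphabet),
              dimnames = list(pat, .seq_alphabet))
  m["A", "A"] <- TRUE
  m["C", "C"] <- TRUE
  m["G", "G"] <- TRUE
  m["T", "T"] <- TRUE
  m["W", c("A", "T")] <- TRUE
  m["R", c("A", "G")] <- TRUE
  m["N", ] <- TRUE
  m
})

.check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .seq_alphabet)
  if (length(bad) > 0) {
    abort(paste0("Sequence contains letters outside {A,C,G,T,N}: ",
                 paste(bad, collapse = ", ")))
  }
  sequence
}

#' Define a degenerate consensus motif
#'
#' @param name Motif name.
#' @param pattern Consensus over the alphabet A, C, G, T, W (A/T), R (A/G),
#'   N (any base).
#' @param max_mismatch Default mismatch tolerance when scanning.
#' @param core A string of `1`/`0` of the same length as `pattern` marking
#'   core positions (mismatches there are ranked as more damaging than flank
#'   mismatches); `NULL` marks every position as core.
#' @return An object of class `consensus_motif`.
#' @examples
#' consensus_motif("CArG", "CCWWWWWWGG", max_mismatch = 1,
#'                 core = "0011111100")
#' @export
consensus_motif <- function(name, pattern, max_mismatch = 0, core = NULL) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) abort("`pattern` must be nonempty.")
  letters_ <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters_), rownames(.match_table))
  if (length(bad) > 0) {
    abort(paste0("Pattern letters outside {A,C,G,T,W,R,N}: ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(core)) core <- strrep("1", nchar(pattern))
  if (nchar(core) != nchar(pattern)) {
    abort("`core` must have the same length as `pattern`.")
  }
  core_mask <- strsplit(core, "", fixed = TRUE)[[1]] == "1"
  if (max_mismatch < 0) abort("`max_mismatch` must be nonnegative.")
  structure(
    list(name = name, pattern = pattern, max_mismatch = as.integer(max_mismatch),
         core_mask = core_mask),
    class = "consensus_motif"
  )
}

#' @export
print.consensus_motif <- function(x, ...) {
  core <- paste(ifelse(x$core_mask, "*", "."), collapse = "")
  cat(sprintf("<consensus_motif> %s: %s (core %s, max_mm %d)\n",
              x$name, x$pattern, core, x$max_mismatch))
  invisible(x)
}

#' Built-in promoter motif registry
#'
#' The default motifs scanned in smooth-muscle promoter analysis:
#' \describe{
#'   \item{CArG}{SRF-binding CArG box, consensus `CCWWWWWWGG`; the six-W
#'     A/T track is the core, the `CC`/`GG` dinucleotides the flank; one
#'     mismatch tolerated by default (to admit "CArG-like" elements).}
#'   \item{MCAT}{TEAD-binding element `CATTCCT` (YAP/TAZ act through it).}
#'   \item{GATA}{canonical `WGATAR`.}
#'   \item{GRE}{glucocorticoid receptor half-site `TGTTCT` (scanning both
#'     strands also covers `AGAACA`).}
#' }
#'
#' @param overrides Optional named list; each element is a list of fields
#'   (`pattern`, `max_mismatch`, `core`) replacing those of the named motif,
#'   or a whole [consensus_motif()] to add/replace.
#' @return A named list of `consensus_motif` objects.
#' @export
builtin_motifs <- function(overrides = NULL) {
  reg <- list(
    CArG = consensus_motif("CArG", "CCWWWWWWGG", max_mismatch = 1,
                           core = "0011111100"),
    MCAT = consensus_motif("MCAT", "CATTCCT", max_mismatch = 0),
    GATA = consensus_motif("GATA", "WGATAR", max_mismatch = 0),
    GRE  = consensus_motif("GRE", "TGTTCT", max_mismatch = 0)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      if (inherits(ov, "consensus_motif")) {
        reg[[nm]] <- ov
      } else {
        cur <- reg[[nm]]
        if (is.null(cur)) abort(paste0("Unknown motif to override: ", nm))
        pattern <- ov$pattern %||% cur$pattern
        # a replacement pattern invalidates the stored core mask unless a new
        # one is supplied alongside it
        core <- ov$core %||% (
          if (nchar(pattern) == length(cur$core_mask)) {
            paste(as.integer(cur$core_mask), collapse = "")
          } else {
            NULL
          }
        )
        reg[[nm]] <- consensus_motif(
          nm,
          pattern = pattern,
          max_mismatch = ov$max_mismatch %||% cur$max_mismatch,
          core = core
        )
      }
    }
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a motif registry
#'
#' @param motifs Named list of [consensus_motif()] objects.
#' @param path File path for the JSON registry.
#' @return `read_motif_registry()` returns the named motif list.
#' @export
write_motif_registry <- function(motifs, path) {
  entries <- purrr::map(motifs, function(m) {
    list(name = m$name, pattern = m$pattern,
         max_mismatch = m$max_mismatch,
         core = paste(as.integer(m$core_mask), collapse = ""))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_motif_registry
#' @export
read_motif_registry <- function(path) {
  entries <- jsonlite::read_json(path)
  purrr::map(entries, function(e) {
    consensus_motif(e$name, e$pattern, e$max_mismatch, e$core)
  })
}

#' Per-position mismatch profile of a window against a motif
#'
#' Degenerate pattern letters match their expansion (W = A/T, R = A/G,
#' N = any). Mismatch counts are split into core and flank according to the
#' motif's core mask.
#'
#' @param window Sequence window, same length as the motif pattern.
#' @param motif A [consensus_motif()].
#' @return A tibble with one row: `mm_total`, `mm_core`, `mm_flank`.
#' @examples
#' carg <- builtin_motifs()$CArG
#' mismatch_profile("ACTTTTATGG", carg)  # flank mismatch: (1, 0, 1)
#' mismatch_profile("CCAGATATGG", carg)  # core mismatch:  (1, 1, 0)
#' @export
mismatch_profile <- function(window, motif) {
  window <- .check_sequence(window)
  if (nchar(window) != nchar(motif$pattern)) {
    abort("`window` must have the same length as the motif pattern.")
  }
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  p <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  ok <- .match_table[cbind(p, w)]
  tibble(
    mm_total = sum(!ok),
    mm_core = sum(!ok & motif$core_mask),
    mm_flank = sum(!ok & !motif$core_mask)
  )
}

#' Convert between sequence offsets and signed TSS-relative positions
#'
#' Positions are 1-based and signed with no zero: the TSS base itself is
#' `+1`, the base immediately upstream is `-1`. `tss_index` is the 1-based
#' index of the TSS base within the sequence.
#'
#' @param offset 1-based offset within the sequence.
#' @param tss_index 1-based index of the TSS base.
#' @param position Signed TSS-relative position (nonzero).
#' @return `to_tss_coordinates()` returns the signed position;
#'   `from_tss_coordinates()` its exact inverse.
#' @examples
#' to_tss_coordinates(801, 801)  # +1
#' to_tss_coordinates(800, 801)  # -1
#' from_tss_coordinates(57, 801) # 857
#' @export
to_tss_coordinates <- function(offset, tss_index) {
  ifelse(offset >= tss_index, offset - tss_index + 1L, offset - tss_index)
}

#' @rdname to_tss_coordinates
#' @export
from_tss_coordinates <- function(position, tss_index) {
  if (any(position == 0)) abort("Signed TSS positions are never 0.")
  ifelse(position > 0, tss_index + position - 1L, tss_index + position)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over Biostrings; kept exported because TSS-relative minus
#' strand plantings and scans both need it.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# Mismatch counts for every window of `codes` (integer-coded sequence)
# against a motif. direction "fwd" compares windows as read; "rev" compares
# the reverse complement of each window (minus-strand match) without
# materializing revcomp strings.
.window_mismatches <- function(codes, motif, direction = c("fwd", "rev")) {
  direction <- match.arg(direction)
  len <- nchar(motif$pattern)
  n_win <- length(codes) - len + 1L
  if (n_win < 1) return(NULL)
  p <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  if (direction == "rev") {
    # complement codes (A<->T, C<->G, N fixed) and read windows 3'->5'
    comp <- c(4L, 3L, 2L, 1L, 5L)
    codes <- comp[codes]
    idx <- outer(rev(seq_len(len)), seq_len(n_win) - 1L, "+")
  } else {
    idx <- outer(seq_len(len), seq_len(n_win) - 1L, "+")
  }
  seq_letters <- .seq_alphabet[codes[idx]]
  ok <- matrix(.match_table[cbind(rep(p, n_win), seq_letters)], nrow = len)
  list(
    mm_total = colSums(!ok),
    mm_core = colSums((!ok) & motif$core_mask)
  )
}

#' Scan a promoter for a degenerate motif
#'
#' Slides the motif over every window of the sequence; windows with at most
#' `max_mismatch` mismatches are reported. For the minus strand the reverse
#' complement of each window is compared against the pattern, so coordinates
#' are always given on the plus strand as the 5'-most base of the window,
#' converted to signed TSS-relative positions. Hits are sorted by position,
#' then strand.
#'
#' @param sequence Promoter sequence (A, C, G, T, N; lowercase accepted).
#' @param motif A [consensus_motif()].
#' @param tss_index 1-based index of the TSS base within `sequence`.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param max_mismatch Mismatch tolerance; defaults to the motif's own.
#' @return A tibble of hits: `motif`, `tss_position`, `strand`,
#'   `matched_sequence` (the motif-strand sequence of the window),
#'   `mm_total`, `mm_core`, `mm_flank`.
#' @export
scan_promoter <- function(sequence, motif, tss_index,
                          strands = c("both", "+", "-"),
                          max_mismatch = NULL) {
  strands <- match.arg(strands)
  sequence <- .check_sequence(sequence)
  len <- nchar(motif$pattern)
  if (nchar(sequence) < len) abort("Sequence shorter than the motif pattern.")
  if (tss_index < 1 || tss_index > nchar(sequence)) {
    abort("`tss_index` outside the sequence.")
  }
  max_mm <- max_mismatch %||% motif$max_mismatch

  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1]], .seq_alphabet)
  out <- list()
  for (st in intersect(c("+", "-"), if (strands == "both") c("+", "-") else strands)) {
    mm <- .window_mismatches(codes, motif,
                             direction = if (st == "+") "fwd" else "rev")
    keep <- which(mm$mm_total <= max_mm)
    if (length(keep) == 0) next
    windows <- substring(sequence, keep, keep + len - 1L)
    if (st == "-") windows <- vapply(windows, reverse_complement, character(1))
    out[[st]] <- tibble(
      motif = motif$name,
      tss_position = as.integer(to_tss_coordinates(keep, tss_index)),
      strand = st,
      matched_sequence = unname(windows),
      mm_total = as.integer(mm$mm_total[keep]),
      mm_core = as.integer(mm$mm_core[keep]),
      mm_flank = as.integer(mm$mm_total[keep] - mm$mm_core[keep])
    )
  }
  if (length(out) == 0) {
    return(tibble(
      motif = character(), tss_position = integer(), strand = character(),
      matched_sequence = character(), mm_total = integer(),
      mm_core = integer(), mm_flank = integer()
    ))
  }
  bind_rows(out) %>% arrange(.data$tss_position, .data$strand)
}

#' Scan a table of promoters for a set of motifs
#'
#' @param promoters A data frame with columns `id`, `sequence`, `tss_index`
#'   (as returned by [read_promoters()] or built by hand).
#' @param motifs Named list of [consensus_motif()] objects
#'   (default [builtin_motifs()]).
#' @param strands,max_mismatch Passed to [scan_promoter()]; `max_mismatch`
#'   may be a named vector of per-motif tolerances.
#' @return A tibble of hits with a leading `promoter_id` column.
#' @export
scan_motifs <- function(promoters, motifs = builtin_motifs(),
                        strands = "both", max_mismatch = NULL) {
  stopifnot(all(c("id", "sequence", "tss_index") %in% names(promoters)))
  purrr::pmap(promoters[c("id", "sequence", "tss_index")], function(id, sequence, tss_index) {
    purrr::map(motifs, function(m) {
      mm <- if (is.null(max_mismatch)) NULL else unname(max_mismatch[m$name])
      if (length(mm) == 0 || is.na(mm)) mm <- NULL
      scan_promoter(sequence, m, tss_index, strands = strands,
                    max_mismatch = mm)
    }) %>% bind_rows()
  }) %>%
    purrr::map2(promoters$id, ., function(id, hits) mutate(hits, promoter_id = id)) %>%
    bind_rows() %>%
    select("promoter_id", dplyr::everything())
}

#' Rank CArG hits by CArG-likeness
#'
#' A flank (CC/GG) mismatch is less damaging than a core (A/T-track)
#' mismatch: the ordering key is core mismatches ascending, then total
#' mismatches ascending, then absolute TSS distance ascending. At equal
#' mismatch profiles the hit closest to the TSS ranks first.
#'
#' @param hits A tibble of hits from a single motif (typically the CArG scan).
#' @return The hits reordered, best CArG match first.
#' @export
rank_carg_hits <- function(hits) {
  if (nrow(hits) > 0 && dplyr::n_distinct(hits$motif) > 1) {
    abort("`hits` mixes several motifs; rank one motif at a time.")
  }
  arrange(hits, .data$mm_core, .data$mm_total, abs(.data$tss_position))
}
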