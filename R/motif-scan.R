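# TAAT-core cis-element cluster scanner.  Homeodomain binding sites share
# the TAAT core; the CLV3 CRM is five such cores within ~110 bp.  The
# published clustering algorithm lives in unavailable supplementary text,
# so this module is a parameterised stand-in whose defaults
# (min_cores = 3, window_bp = 60) are chosen to detect the CLV3 CRM
# itself (five cores, maximum inter-core gap 53 bp).
# Coordinates are 0-based, half-open (BED convention) throughout.

#' Find TAAT cores on both strands
#'
#' Reports every occurrence of `TAAT` on the forward strand and of its
#' reverse complement `ATTA` (i.e. `TAAT` read on the reverse strand) at
#' forward-strand coordinates.  Matching is case-insensitive; `N` never
#' matches; overlapping matches are all reported.
#'
#' @param sequence A DNA string over `{A, C, G, T, N}` (or a
#'   [Biostrings::DNAString]).
#' @return Tibble of core hits: `start` (0-based), `end`
#'   (half-open, `start + 4`), `strand` (`"+"`/`"-"`), `core` (the
#'   forward-strand text of the site), sorted by `start` then strand.
#' @examples
#' find_cores("TAATAAT")  # + hits at 0 and 3
#' @export
find_cores <- function(sequence) {
  if (inherits(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) > 0 &&
      grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A, C, G, T, N}",
         call. = FALSE)
  }
  dna <- Biostrings::DNAString(if (nchar(sequence) == 0) "" else sequence)
  hit_tbl <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, dna)
    if (length(m) == 0) {
      return(tibble::tibble(start = integer(), end = integer(),
                            strand = character(), core = character()))
    }
    tibble::tibble(start = BiocGenerics::start(m) - 1L,
                   end = BiocGenerics::end(m),
                   strand = strand,
                   core = as.character(m))
  }
  out <- dplyr::bind_rows(hit_tbl("TAAT", "+"), hit_tbl("ATTA", "-"))
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Group core hits into clusters
#'
#' Maximal runs of hits in which each consecutive pair is at most
#' `window_bp` apart (start-to-start), kept only when the run holds at
#' least `min_cores` hits.  Cluster intervals are tight: they begin at
#' the first member's start and end at the last member's end.  Clusters
#' are maximal by construction (no adjacent hit within `window_bp` is
#' left out) and non-overlapping.
#'
#' @param hits A [find_cores()] tibble (any extra columns are ignored).
#' @param min_cores Minimum hits per cluster (>= 2).
#' @param window_bp Maximum allowed gap between consecutive member starts
#'   (>= 4).
#' @return Tibble of clusters: `start`, `end` (0-based half-open),
#'   `n_cores`.
#' @examples
#' hits <- tibble::tibble(start = c(0, 20, 47, 57, 110))
#' hits$end <- hits$start + 4L
#' find_clusters(hits, min_cores = 3, window_bp = 60)
#' @export
find_clusters <- function(hits, min_cores = 3, window_bp = 60) {
  if (min_cores < 2) stop("`min_cores` must be >= 2", call. = FALSE)
  if (window_bp < 4) stop("`window_bp` must be >= 4", call. = FALSE)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          n_cores = integer())
  if (nrow(hits) == 0) return(empty)
  # duplicate coordinates (both-strand palindromic hits) count once for
  # spacing but all members are counted
  starts <- sort(hits$start)
  ends <- hits$end[order(hits$start)]
  breaks <- which(diff(starts) > window_bp)
  group <- cumsum(c(1L, as.integer(seq_along(starts)[-1] %in% (breaks + 1L))))
  out <- tibble::tibble(start = starts, end = ends, group = group) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_cores = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_cores >= min_cores) |>
    dplyr::select("start", "end", "n_cores")
  if (nrow(out) == 0) empty else out
}

#' Scan a FASTA file for TAAT-core clusters
#'
#' @param path Path to a FASTA file (uncompressed or gzipped).
#' @param min_cores,window_bp Clustering parameters, see
#'   [find_clusters()].
#' @return BED-like tibble: `record`, `start`, `end`, `n_cores`,
#'   `strand` (always `"."` — clusters pool both strands).  Empty input
#'   gives an empty tibble.
#' @export
scan_fasta <- function(path, min_cores = 3, window_bp = 60) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("cannot read FASTA at ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  empty <- tibble::tibble(record = character(), start = integer(),
                          end = integer(), n_cores = integer(),
                          strand = character())
  if (length(seqs) == 0) return(empty)
  rows <- purrr::imap(as.character(seqs), function(s, nm) {
    cl <- tryCatch(
      find_clusters(find_cores(s), min_cores, window_bp),
      error = function(e) {
        stop("record \"", nm, "\": ", conditionMessage(e), call. = FALSE)
      })
    if (nrow(cl) == 0) return(NULL)
    dplyr::mutate(cl, record = nm, strand = ".", .before = 1) |>
      dplyr::relocate("record", "start", "end", "n_cores", "strand")
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) empty else out
}
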