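# MicroRNA seed-site prediction on annotated transcripts.
#
# A seed site is a 7-nt window on the transcript (read 5'->3') that pairs
# with nucleotides 2-8 of the mature microRNA in an antiparallel duplex,
# i.e. the window equals the reverse complement of the seed up to the
# allowed number of mismatches.  All coordinates are 1-based inclusive on
# the transcript.

RNA_LEVELS <- c("A", "C", "G", "U")

# Watson-Crick pairing lookup over integer-encoded RNA (A=1 C=2 G=3 U=4)
wc_pair_matrix <- function(allow_wobble = FALSE) {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_LEVELS, RNA_LEVELS))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_wobble) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

# normalize a nucleotide string to the RNA alphabet; DNA input (T) is
# transcribed with a warning
as_rna_chars <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (any(chars == "T")) {
    warning(sprintf("%s contains T: auto-converted to U (RNA alphabet)",
                    what), call. = FALSE)
    chars[chars == "T"] <- "U"
  }
  bad <- setdiff(unique(chars), RNA_LEVELS)
  if (length(bad) > 0) {
    stop_fmt("%s contains invalid character(s): %s", what,
             paste(bad, collapse = ", "))
  }
  chars
}

rna_int <- function(chars) match(chars, RNA_LEVELS)

rna_complement <- function(chars) {
  c(A = "U", C = "G", G = "C", U = "A")[chars]
}

#' Construct a mature microRNA record
#'
#' @param id MicroRNA identifier (e.g. `"hsa-miR-99a"`).
#' @param sequence Mature sequence 5'->3'; DNA input is transcribed to RNA
#'   with a warning. Must be at least 16 nt.
#' @return A list of class `mature_mirna` with `id` and `sequence`.
#' @export
mature_mirna <- function(id, sequence) {
  chars <- as_rna_chars(sequence, sprintf("miRNA %s", id))
  if (length(chars) < 16) {
    stop_fmt("miRNA %s is %d nt; mature microRNAs must be >= 16 nt",
             id, length(chars))
  }
  structure(list(id = id, sequence = paste(chars, collapse = "")),
            class = "mature_mirna")
}

#' Construct an annotated transcript
#'
#' @param gene_id Gene/transcript identifier.
#' @param sequence Nucleotide sequence 5'->3' (DNA accepted, transcribed
#'   internally).
#' @param regions Data frame with columns `label` (`5UTR`/`CDS`/`3UTR`),
#'   `start`, `end` (1-based inclusive transcript coordinates);
#'   non-overlapping, ordered, within bounds.
#' @return A list of class `transcript_regions`.
#' @export
transcript_regions <- function(gene_id, sequence, regions) {
  chars <- suppressWarnings(
    as_rna_chars(sequence, sprintf("transcript %s", gene_id)))
  stopifnot(is.data.frame(regions),
            all(c("label", "start", "end") %in% names(regions)))
  check_levels(regions$label, c("5UTR", "CDS", "3UTR"), "region label")
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(regions$start > regions$end) || any(regions$start < 1) ||
      any(regions$end > length(chars))) {
    stop_fmt("transcript %s: region spans out of bounds", gene_id)
  }
  if (nrow(regions) > 1 &&
      any(regions$start[-1] <= regions$end[-nrow(regions)])) {
    stop_fmt("transcript %s: overlapping region spans", gene_id)
  }
  structure(list(gene_id = gene_id,
                 sequence = paste(chars, collapse = ""),
                 regions = regions[, c("label", "start", "end")]),
            class = "transcript_regions")
}

#' Extract the seed of a mature microRNA
#'
#' By the canonical definition the seed is nucleotides 2-8 (1-based,
#' 5'->3') of the mature sequence.
#'
#' @param mirna A `mature_mirna` (or plain RNA string).
#' @param first,last Seed span (defaults 2 and 8).
#' @return The seed as an RNA string 5'->3'.
#' @examples
#' extract_seed(mature_mirna("mir", "AACCCGUAGAUCCGAUCUUGUG"))  # "ACCCGUA"
#' @export
extract_seed <- function(mirna, first = 2, last = 8) {
  seq <- if (inherits(mirna, "mature_mirna")) mirna$sequence else
    paste(as_rna_chars(mirna, "miRNA"), collapse = "")
  if (nchar(seq) < last) {
    stop_fmt("sequence length %d < seed end %d", nchar(seq), last)
  }
  substr(seq, first, last)
}

# region containing a transcript position (label or NA)
region_at <- function(tr, pos) {
  r <- tr$regions
  hit <- which(r$start <= pos & pos <= r$end)
  if (length(hit) == 0) NA_character_ else r$label[hit[1]]
}

#' Find microRNA seed sites on a transcript
#'
#' Scans every 7-nt window of the transcript and counts positions at which
#' the window fails to pair with the seed (miRNA nt 2-8) in an antiparallel
#' duplex; windows with at most `max_mismatch` failures are reported.
#' Equivalently, the mismatch count is the Hamming distance between the
#' window (5'->3') and the reverse complement of the seed when only
#' Watson-Crick pairs are allowed; with `allow_wobble` G:U pairs also count
#' as matches. The site region is the one containing the window midpoint;
#' windows straddling a region boundary carry `boundary = TRUE`.
#'
#' @param mirna A `mature_mirna`.
#' @param tr A `transcript_regions`.
#' @param max_mismatch Maximum mismatches in the seed duplex (0, 1 or 2).
#' @param allow_wobble Count G:U wobble pairs as matches (default FALSE).
#' @return A data frame of sites sorted by position with columns
#'   `mirna_id`, `gene_id`, `start`, `end`, `region`, `boundary`,
#'   `mismatches`, `supplementary_score`, `site_seq`.
#' @export
find_seed_sites <- function(mirna, tr, max_mismatch = 2,
                            allow_wobble = FALSE) {
  stopifnot(inherits(mirna, "mature_mirna"),
            inherits(tr, "transcript_regions"),
            max_mismatch %in% 0:2)
  tchars <- strsplit(tr$sequence, "")[[1]]
  n <- length(tchars)
  if (n < 7) stop_fmt("transcript %s shorter than a seed window", tr$gene_id)
  seed <- strsplit(extract_seed(mirna), "")[[1]]
  pairs <- wc_pair_matrix(allow_wobble)
  t_int <- rna_int(tchars)
  seed_int <- rna_int(seed)

  n_win <- n - 6
  matches <- matrix(FALSE, n_win, 7)
  for (k in 1:7) {
    # window position k (5'->3') opposes seed position 8-k in the duplex
    matches[, k] <- pairs[cbind(t_int[k:(n_win + k - 1)], seed_int[8 - k])]
  }
  mism <- 7 - rowSums(matches)
  keep <- which(mism <= max_mismatch)
  if (length(keep) == 0) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      region = character(), boundary = logical(),
                      mismatches = integer(),
                      supplementary_score = integer(),
                      site_seq = character(), stringsAsFactors = FALSE))
  }
  start <- keep
  end <- keep + 6L
  mid <- start + 3L
  region <- vapply(mid, function(p) region_at(tr, p), character(1))
  boundary <- vapply(seq_along(keep), function(i) {
    !identical(region_at(tr, start[i]), region_at(tr, end[i]))
  }, logical(1))
  site_seq <- vapply(seq_along(keep), function(i) {
    paste(tchars[start[i]:end[i]], collapse = "")
  }, character(1))
  out <- data.frame(mirna_id = mirna$id, gene_id = tr$gene_id,
                    start = start, end = end, region = region,
                    boundary = boundary, mismatches = as.integer(mism[keep]),
                    supplementary_score = NA_integer_,
                    site_seq = site_seq, stringsAsFactors = FALSE)
  out$supplementary_score <- vapply(seq_len(nrow(out)), function(i) {
    score_3prime_supplementary(mirna, tr, out[i, , drop = FALSE])
  }, integer(1))
  out
}

#' Score 3'-supplementary pairing for a seed site
#'
#' Counts Watson-Crick pairs between miRNA positions in the supplementary
#' window (default nt 13-16) and the transcript nucleotides opposite them
#' in a linear duplex anchored at the seed match. With a loop allowance of
#' `loop_offset` nucleotides, miRNA position p opposes transcript position
#' `site_end + 2 - p - loop_offset`.
#'
#' @param mirna A `mature_mirna`.
#' @param tr A `transcript_regions`.
#' @param site One site row as returned by [find_seed_sites()] (needs
#'   `end`), or a list with an `end` element.
#' @param window Integer positions on the miRNA (default `13:16`).
#' @param loop_offset Extra unpaired target nucleotides between seed and
#'   supplementary helix (default 0).
#' @return Integer pairing count in `[0, length(window)]`.
#' @export
score_3prime_supplementary <- function(mirna, tr, site, window = 13:16,
                                       loop_offset = 0) {
  stopifnot(inherits(mirna, "mature_mirna"),
            inherits(tr, "transcript_regions"))
  mchars <- strsplit(mirna$sequence, "")[[1]]
  if (max(window) > length(mchars)) {
    stop_fmt("supplementary window %d-%d extends beyond miRNA length %d",
             min(window), max(window), length(mchars))
  }
  tchars <- strsplit(tr$sequence, "")[[1]]
  pairs <- wc_pair_matrix(FALSE)
  end <- site$end
  score <- 0L
  for (p in window) {
    tpos <- end + 2L - p - loop_offset
    if (tpos < 1 || tpos > length(tchars)) next
    if (pairs[mchars[p], tchars[tpos]]) score <- score + 1L
  }
  score
}

#' Render a seed-site alignment as fixed-width text
#'
#' Three lines: the transcript segment 5'->3', a match line with `*` at
#' Watson-Crick paired positions, and the miRNA 3'->5'. The seed span
#' (miRNA nt 2-8) is underlined by a fourth line of carets. Output is
#' deterministic for fixed input.
#'
#' @param mirna A `mature_mirna`.
#' @param tr A `transcript_regions`.
#' @param site One site row from [find_seed_sites()].
#' @return A single string (lines separated by `\n`).
#' @export
render_alignment <- function(mirna, tr, site) {
  mchars <- strsplit(mirna$sequence, "")[[1]]
  tchars <- strsplit(tr$sequence, "")[[1]]
  L <- length(mchars)
  pairs <- wc_pair_matrix(FALSE)
  end <- site$end
  # miRNA shown 3'->5': column j holds miRNA position L + 1 - j, which
  # opposes transcript position end + 1 - L + j
  tline <- mline <- stars <- seedmark <- character(L)
  for (j in seq_len(L)) {
    p <- L + 1L - j
    tpos <- end + 1L - L + j
    mline[j] <- mchars[p]
    if (tpos >= 1 && tpos <= length(tchars)) {
      tline[j] <- tchars[tpos]
      stars[j] <- if (pairs[mchars[p], tchars[tpos]]) "*" else " "
    } else {
      tline[j] <- "-"
      stars[j] <- " "
    }
    seedmark[j] <- if (p >= 2 && p <= 8) "^" else " "
  }
  paste(
    sprintf("%s 5'-%s-3'", format(tr$gene_id, width = 12),
            paste(tline, collapse = "")),
    sprintf("%s    %s", format("", width = 12),
            paste(stars, collapse = "")),
    sprintf("%s 3'-%s-5'", format(mirna$id, width = 12),
            paste(mline, collapse = "")),
    sprintf("%s    %s  (seed)", format("", width = 12),
            paste(seedmark, collapse = "")),
    sep = "\n")
}

#' Locate a site relative to the 3'UTR
#'
#' Reports the region containing the site and, for sites 5' of the 3'UTR,
#' the gap in nucleotides between the site end and the nucleotide just
#' before the 3'UTR start (a site ending at position 100 with the 3'UTR
#' starting at 199 lies 98 nt 5'-adjacent to the 3'UTR).
#'
#' @param site One site row from [find_seed_sites()].
#' @param tr A `transcript_regions`.
#' @return A list with `region` and `distance_to_3utr` (0 inside the
#'   3'UTR, `NA` when no 3'UTR is annotated or the site is 3' of it).
#' @export
annotate_site_position <- function(site, tr) {
  stopifnot(inherits(tr, "transcript_regions"))
  region <- region_at(tr, site$start + 3L)
  r3 <- tr$regions[tr$regions$label == "3UTR", , drop = FALSE]
  if (nrow(r3) == 0) {
    return(list(region = region, distance_to_3utr = NA_real_))
  }
  utr_start <- r3$start[1]
  dist <- if (site$start >= utr_start) {
    0
  } else if (site$end < utr_start) {
    utr_start - 1 - site$end
  } else {
    0  # straddles the boundary
  }
  list(region = region, distance_to_3utr = dist)
}

#' Read mature microRNAs from FASTA
#'
#' @param path FASTA file of mature sequences (RNA or DNA alphabet).
#' @return A list of `mature_mirna` objects named by FASTA id.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    mature_mirna(ids[i], as.character(set[[i]]))
  })
  names(out) <- ids
  out
}

#' Read annotated transcripts from FASTA plus a region table
#'
#' @param fasta_path Transcript FASTA.
#' @param regions_path TSV with columns `gene_id`, `label`, `start`, `end`.
#' @return A named list of `transcript_regions` objects.
#' @export
read_transcripts <- function(fasta_path, regions_path) {
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  reg <- utils::read.table(regions_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("gene_id", "label", "start", "end")
  if (!all(needed %in% names(reg))) {
    stop_fmt("region table must have columns %s",
             paste(needed, collapse = ", "))
  }
  out <- lapply(seq_along(set), function(i) {
    transcript_regions(ids[i], as.character(set[[i]]),
                       reg[reg$gene_id == ids[i], , drop = FALSE])
  })
  names(out) <- ids
  out
}
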