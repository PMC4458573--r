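IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Allowed sequence letters for one consensus letter.  An assembled-gap "N"
# in the subject sequence is only accepted where the consensus itself says
# "anything" (conservative for gaps).
allowed_set <- function(code) {
  s <- IUPAC_SETS[[code]]
  if (code == "N") c(s, "N") else s
}

complement_set <- function(bases) {
  unname(chartr("ACGTN", "TGCAN", bases))
}

#' Parse a degenerate IUPAC consensus
#'
#' The consensus may contain one parenthesised optional base, e.g. the root
#' hair element `"WHHDTGNNN(N)KCACGWH"` which matches both a 16-mer (without
#' the optional `N`) and a 17-mer (with it).
#'
#' @param raw Consensus string of IUPAC codes with at most one `(X)` group.
#' @return An object of class `iupac_consensus` with the expanded match
#'   lengths and per-position allowed base sets for each length variant.
#' @export
#' @examples
#' parse_consensus("WHHDTGNNN(N)KCACGWH")$lengths  # 16 17
parse_consensus <- function(raw) {
  if (stringr::str_count(raw, stringr::fixed("(")) > 1L ||
      stringr::str_count(raw, stringr::fixed(")")) > 1L) {
    stop_rhe("consensus may contain at most one (X) optional group",
             "bad_consensus")
  }
  m <- stringr::str_match(raw, "^([A-Z]*)(?:\\(([A-Z]+)\\))?([A-Z]*)$")
  if (is.na(m[1, 1])) {
    stop_rhe(sprintf("malformed consensus '%s'", raw), "bad_consensus")
  }
  pre <- m[1, 2]; opt <- m[1, 3]; post <- m[1, 4]
  if (!is.na(opt) && nchar(opt) != 1L) {
    stop_rhe("optional group must contain exactly one letter", "bad_consensus")
  }
  letters_of <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
  all_letters <- c(letters_of(pre), if (!is.na(opt)) opt, letters_of(post))
  unknown <- setdiff(all_letters, names(IUPAC_SETS))
  if (length(unknown) > 0L) {
    stop_rhe(sprintf("unknown IUPAC letter '%s'", unknown[1L]), "bad_consensus")
  }
  short <- c(letters_of(pre), letters_of(post))
  variants <- list()
  variants[[as.character(length(short))]] <- lapply(short, allowed_set)
  if (!is.na(opt)) {
    long <- c(letters_of(pre), opt, letters_of(post))
    variants[[as.character(length(long))]] <- lapply(long, allowed_set)
  }
  structure(
    list(raw = raw, lengths = sort(as.integer(names(variants))),
         variants = variants,
         code_map = IUPAC_SETS[unique(all_letters)]),
    class = "iupac_consensus"
  )
}

#' Test a consensus match at one position
#'
#' @param seq Subject sequence (A/C/G/T/N string).
#' @param pos 1-based position of the window's leftmost base in `seq`.
#' @param consensus An [parse_consensus()] object.
#' @param length Which length variant to test (one of `consensus$lengths`).
#' @param orientation `"+"` tests the window as read; `"-"` tests its
#'   reverse complement against the consensus.
#' @return `TRUE` iff every window base is allowed at its consensus position.
#' @export
match_at <- function(seq, pos, consensus, length = max(consensus$lengths),
                     orientation = "+") {
  stopifnot(inherits(consensus, "iupac_consensus"))
  if (!length %in% consensus$lengths) {
    stop_rhe(sprintf("length %d is not a variant of this consensus", length),
             "bad_argument")
  }
  if (pos < 1L || pos + length - 1L > nchar(seq)) return(FALSE)
  window <- toupper(substr(seq, pos, pos + length - 1L))
  if (orientation == "-") window <- revcomp_chr(window)
  sets <- consensus$variants[[as.character(length)]]
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  all(vapply(seq_len(length), function(i) ch[i] %in% sets[[i]], logical(1)))
}

# Vectorised sliding scan of one allowed-set pattern over a character vector.
scan_pattern <- function(chars, sets) {
  L <- length(sets)
  n <- length(chars)
  if (n < L) return(integer(0))
  hit <- rep(TRUE, n - L + 1L)
  for (i in seq_len(L)) {
    hit <- hit & chars[i:(n - L + i)] %in% sets[[i]]
    if (!any(hit)) return(integer(0))
  }
  which(hit)
}

#' Scan one region sequence for consensus matches on both strands
#'
#' Forward hits are reported with ascending `start < end`.  A reverse hit is
#' a window whose reverse complement matches the consensus; it is reported
#' with `start > end` (descending coordinates) and `matched_seq` equal to
#' the region-strand window text, mirroring how the study prints its
#' reverse-orientation rows.  Both length variants are scanned; overlapping
#' hits are all reported, and duplicates are collapsed by
#' (orientation, leftmost position, length).
#'
#' @param seq Region sequence (A/C/G/T/N string), local coordinate 1 at its
#'   5' end.
#' @param consensus An [parse_consensus()] object.
#' @param both_strands Scan the reverse orientation too (default `TRUE`).
#' @return Tibble with columns `start`, `end`, `orientation`, `matched_seq`,
#'   `width`.
#' @export
scan_region <- function(seq, consensus, both_strands = TRUE) {
  stopifnot(inherits(consensus, "iupac_consensus"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- list()
  for (L in consensus$lengths) {
    sets <- consensus$variants[[as.character(L)]]
    fwd <- scan_pattern(chars, sets)
    if (length(fwd) > 0L) {
      out[[length(out) + 1L]] <- tibble(
        start = fwd, end = fwd + L - 1L, orientation = "+",
        matched_seq = substring(seq, fwd, fwd + L - 1L), width = L
      )
    }
    if (both_strands) {
      rc_sets <- lapply(rev(sets), complement_set)
      rev_hits <- scan_pattern(chars, rc_sets)
      if (length(rev_hits) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          start = rev_hits + L - 1L, end = rev_hits, orientation = "-",
          matched_seq = substring(seq, rev_hits, rev_hits + L - 1L), width = L
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), end = integer(0),
                  orientation = character(0), matched_seq = character(0),
                  width = integer(0)))
  }
  res <- dplyr::mutate(dplyr::bind_rows(out),
                       leftmost = pmin(.data$start, .data$end))
  res <- dplyr::distinct(res, .data$orientation, .data$leftmost, .data$width,
                         .keep_all = TRUE)
  res <- dplyr::arrange(res, .data$orientation, .data$leftmost, .data$width)
  dplyr::select(res, -"leftmost")
}

#' Region-extraction settings for gene scanning
#'
#' @param promoter_len Promoter window length in bp upstream of the start
#'   codon (default 3000, the "-3000 bp" window of the study).
#' @param regions Region classes to scan.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(promoter_len = 3000L,
                        regions = c("promoter", "intron", "cds")) {
  assert_scalar_number(promoter_len, "promoter_len", lower = 1)
  regions <- match.arg(regions, c("promoter", "intron", "cds"),
                       several.ok = TRUE)
  structure(list(promoter_len = as.integer(promoter_len), regions = regions),
            class = "region_spec")
}

# Extract the region sequences of one gene model on its coding strand.
# Returns a list of tibble(region, region_index, seq).
gene_region_seqs <- function(model, genome, spec) {
  if (!model$chrom %in% names(genome)) {
    stop_rhe(sprintf("chromosome '%s' missing from genome", model$chrom),
             "missing_chromosome")
  }
  chrom_seq <- genome[[model$chrom]]
  clen <- nchar(chrom_seq)
  minus <- model$strand == "-"
  take <- function(s, e) {
    txt <- substr(chrom_seq, s, e)
    if (minus) revcomp_chr(txt) else txt
  }
  out <- list()
  sc <- model$start_codon_pos
  if ("promoter" %in% spec$regions && !is.na(sc)) {
    if (minus) {
      s <- sc + 1L; e <- min(clen, sc + spec$promoter_len)
    } else {
      s <- max(1L, sc - spec$promoter_len); e <- sc - 1L
    }
    if (s <= e) {
      out[[length(out) + 1L]] <- tibble(region = "promoter",
                                        region_index = 0L,
                                        seq = take(s, e))
    }
  }
  if ("intron" %in% spec$regions) {
    introns <- model$introns[[1L]]
    if (nrow(introns) > 0L) {
      ord <- if (minus) rev(seq_len(nrow(introns))) else seq_len(nrow(introns))
      for (k in seq_along(ord)) {
        i <- ord[k]
        out[[length(out) + 1L]] <- tibble(region = "intron",
                                          region_index = k,
                                          seq = take(introns[i, 1L],
                                                     introns[i, 2L]))
      }
    }
  }
  if ("cds" %in% spec$regions) {
    cds <- model$cds[[1L]]
    if (nrow(cds) > 0L) {
      ord <- if (minus) rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
      spliced <- paste(vapply(ord, function(i) take(cds[i, 1L], cds[i, 2L]),
                              character(1)), collapse = "")
      out[[length(out) + 1L]] <- tibble(region = "cds", region_index = 0L,
                                        seq = spliced)
    }
  }
  out
}

#' Scan a gene model's promoter, introns and spliced CDS for a consensus
#'
#' Regions are extracted on the coding strand: the promoter is the
#' `promoter_len` bases 5' of the start codon (truncated at the chromosome
#' edge), each intron is scanned separately with `region_index` giving its
#' ordinal in transcription order, and the CDS is the spliced concatenation
#' of CDS segments in translation order (a match straddling an exon-intron
#' boundary in genomic space is therefore only found if it exists in the
#' spliced text).  Hit coordinates are 1-based and local to each region
#' sequence.
#'
#' @param models Gene-model tibble ([read_gff3()] / [gene_model()]); all
#'   rows are scanned.
#' @param genome Named character vector of chromosome sequences
#'   ([read_fasta()]).
#' @param consensus An [parse_consensus()] object.
#' @param spec A [region_spec()].
#' @return Tibble of hits: `gene_id`, `transcript_id`, `region`,
#'   `region_index` (intron ordinal, 0 otherwise), `start`, `end`,
#'   `orientation`, `matched_seq`.
#' @export
scan_gene <- function(models, genome, consensus, spec = region_spec()) {
  hits <- purrr::map(seq_len(nrow(models)), function(i) {
    model <- models[i, ]
    regions <- gene_region_seqs(model, genome, spec)
    purrr::map(regions, function(r) {
      h <- scan_region(r$seq, consensus)
      if (nrow(h) == 0L) return(NULL)
      tibble(gene_id = model$gene_id, transcript_id = model$transcript_id,
             region = r$region, region_index = r$region_index,
             start = h$start, end = h$end, orientation = h$orientation,
             matched_seq = h$matched_seq)
    })
  })
  flat <- dplyr::bind_rows(unlist(hits, recursive = FALSE))
  if (nrow(flat) == 0L) {
    return(tibble(gene_id = character(0), transcript_id = character(0),
                  region = character(0), region_index = integer(0),
                  start = integer(0), end = integer(0),
                  orientation = character(0), matched_seq = character(0)))
  }
  flat
}

#' Summarise per-gene region combinations of motif hits
#'
#' @param hits Hit tibble from [scan_gene()].
#' @return Tibble with per-gene hit counts by region class and a
#'   `combination` label (`"promoter-only"`, `"promoter+intron"`,
#'   `"all-three"`, ...).  Genes without hits are absent.
#' @export
classify_genes <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(gene_id = character(0), n_promoter = integer(0),
                  n_intron = integer(0), n_cds = integer(0),
                  combination = character(0)))
  }
  counts <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene_id),
    n_promoter = sum(.data$region == "promoter"),
    n_intron = sum(.data$region == "intron"),
    n_cds = sum(.data$region == "cds"),
    .groups = "drop"
  )
  label <- function(p, i, cds) {
    present <- c("promoter", "intron", "cds")[c(p, i, cds) > 0]
    if (length(present) == 3L) "all-three"
    else if (length(present) == 1L) paste0(present, "-only")
    else paste(present, collapse = "+")
  }
  counts$combination <- purrr::pmap_chr(
    list(counts$n_promoter, counts$n_intron, counts$n_cds), label)
  counts
}
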