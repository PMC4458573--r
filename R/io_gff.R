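#' Construct a gene model
#'
#' A gene model is one transcript's genomic anatomy: its exons, CDS segments
#' and the derived start-codon position, all as 1-based inclusive genomic
#' intervals (GFF3 convention).  Most users get gene models from
#' [read_gff3()]; this constructor exists for programmatic fixtures.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column integer matrices of `[start, end]` intervals
#'   (1-based, inclusive).  Exons must be disjoint; every CDS segment must lie
#'   inside an exon.
#' @return A one-row tibble with list-columns `exons`, `cds`, `introns` and
#'   the scalar `start_codon_pos` (the genomic coordinate of the first coding
#'   base: minimum CDS start on `+`, maximum CDS end on `-`).
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds = NULL) {
  if (!strand %in% c("+", "-")) {
    stop_rhe(sprintf("unknown strand '%s' for %s", strand, transcript_id),
             "bad_strand")
  }
  exons <- normalise_intervals(exons)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop_rhe(sprintf("overlapping exons in %s", transcript_id), "bad_model")
  }
  if (is.null(cds) || nrow(cds) == 0L) {
    cds <- matrix(integer(0), ncol = 2L)
    start_codon <- NA_integer_
  } else {
    cds <- normalise_intervals(cds)
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1))
    if (!all(inside)) {
      stop_rhe(sprintf("CDS segment outside exon bounds in %s", transcript_id),
               "bad_model")
    }
    start_codon <- if (strand == "+") min(cds[, 1L]) else max(cds[, 2L])
  }
  introns <- derive_introns(exons)
  tibble(
    gene_id = gene_id, transcript_id = transcript_id,
    chrom = chrom, strand = strand,
    exons = list(exons), cds = list(cds), introns = list(introns),
    start_codon_pos = as.integer(start_codon)
  )
}

normalise_intervals <- function(x) {
  x <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  x[order(x[, 1L]), , drop = FALSE]
}

# Introns are the gaps between consecutive sorted exons.
derive_introns <- function(exons) {
  if (nrow(exons) < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = unname(exons[-nrow(exons), 2L]) + 1L,
        end = unname(exons[-1L, 1L]) - 1L)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (TAIR-style GFF3, 1-based inclusive
#' coordinates) into one gene model per mRNA.  Introns are derived as the
#' gaps between sorted exons.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble of gene models, one row per mRNA; see [gene_model()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parent <- gr$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))

  is_mrna <- type %in% c("mRNA", "transcript")
  if (!any(is_mrna)) {
    stop_rhe("no mRNA/transcript features found", "bad_gff3")
  }
  models <- purrr::map(which(is_mrna), function(i) {
    tid <- id[i]
    kids <- which(parent1 == tid)
    ex <- kids[type[kids] == "exon"]
    cd <- kids[type[kids] == "CDS"]
    exons <- cbind(BiocGenerics::start(gr[ex]), BiocGenerics::end(gr[ex]))
    cds <- if (length(cd) > 0L) {
      cbind(BiocGenerics::start(gr[cd]), BiocGenerics::end(gr[cd]))
    } else NULL
    strand_i <- as.character(BiocGenerics::strand(gr[i]))
    if (!strand_i %in% c("+", "-")) {
      stop_rhe(sprintf("unknown strand '%s' for %s", strand_i, tid),
               "bad_strand")
    }
    gene_model(
      gene_id = if (is.na(parent1[i])) tid else parent1[i],
      transcript_id = tid,
      chrom = as.character(GenomeInfoDb::seqnames(gr[i])),
      strand = strand_i,
      exons = exons, cds = cds
    )
  })
  dplyr::bind_rows(models)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; duplicate headers are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record, in
#'   file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop_rhe(sprintf("duplicate FASTA header: %s", nm[duplicated(nm)][1L]),
             "duplicate_header")
  }
  setNames(toupper(as.character(set)), nm)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes,
#' 1-based inclusive coordinates (the format rtracklayer and [read_gff3()]
#' expect back).
#'
#' @param models Gene-model tibble (see [gene_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  feat <- function(chrom, type, s, e, strand, attrs) {
    paste(chrom, "rhepipe", type, s, e, ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    exons <- m$exons[[1L]]
    cds <- m$cds[[1L]]
    span <- c(min(exons[, 1L]), max(exons[, 2L]))
    lines <- c(lines,
      feat(m$chrom, "gene", span[1], span[2], m$strand,
           sprintf("ID=%s", m$gene_id)),
      feat(m$chrom, "mRNA", span[1], span[2], m$strand,
           sprintf("ID=%s;Parent=%s", m$transcript_id, m$gene_id)))
    for (j in seq_len(nrow(exons))) {
      lines <- c(lines, feat(m$chrom, "exon", exons[j, 1], exons[j, 2],
                             m$strand, sprintf("Parent=%s", m$transcript_id)))
    }
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines, feat(m$chrom, "CDS", cds[j, 1], cds[j, 2],
                             m$strand, sprintf("Parent=%s", m$transcript_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
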