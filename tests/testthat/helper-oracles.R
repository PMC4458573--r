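# Independent oracles used to cross-check the implementation.  These are
# written from first principles (explicit loops, closed forms, Biostrings
# for reverse complement) and deliberately share no code with R/.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Expand "PRE(X)POST" into its length variants as letter vectors.
oracle_patterns <- function(raw) {
  short <- gsub("\\([A-Z]\\)", "", raw)
  long <- gsub("[()]", "", raw)
  pats <- list(strsplit(short, "")[[1]])
  if (long != short) pats <- c(pats, list(strsplit(long, "")[[1]]))
  pats
}

oracle_window_match <- function(window, letters) {
  ch <- strsplit(window, "")[[1]]
  length(ch) == length(letters) &&
    all(vapply(seq_along(ch), function(i) {
      ch[i] %in% ORACLE_IUPAC[[letters[i]]]
    }, logical(1)))
}

# Position-by-position brute-force scan, both strands, all length variants.
oracle_scan <- function(seq, raw) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (letters in oracle_patterns(raw)) {
    L <- length(letters)
    if (n < L) next
    for (p in seq_len(n - L + 1L)) {
      window <- substr(seq, p, p + L - 1L)
      if (oracle_window_match(window, letters)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = p, end = p + L - 1L, orientation = "+",
          matched_seq = window, width = L, stringsAsFactors = FALSE)
      }
      if (oracle_window_match(oracle_revcomp(window), letters)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = p + L - 1L, end = p, orientation = "-",
          matched_seq = window, width = L, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

hit_key <- function(d) {
  if (is.null(d) || nrow(d) == 0L) return(character(0))
  sort(paste(d$orientation, pmin(d$start, d$end), d$width %||% nchar(d$matched_seq),
             d$matched_seq))
}

gene_hit_key <- function(d) {
  if (is.null(d) || nrow(d) == 0L) return(character(0))
  sort(paste(d$gene_id, d$region, d$region_index, d$start, d$end,
             d$orientation, d$matched_seq))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive hypergeometric upper tail from binomial coefficients.
oracle_hyper_upper <- function(x, M, K, N) {
  ks <- x:min(M, K)
  sum(choose(K, ks) * choose(N - K, M - ks)) / choose(N, M)
}

# Two-pass product-moment formula.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Literal three-predicate evaluation of the DE filter on one record.
oracle_de_pass <- function(rpkm_rh, rpkm_nrh, q, status,
                           q_max = 0.05, min_fold = 2, min_rpkm = 1) {
  if (status != "OK" || is.na(q)) return(FALSE)
  ratio <- if (rpkm_rh == 0 && rpkm_nrh == 0) return(FALSE)
           else if (rpkm_rh == 0 || rpkm_nrh == 0) Inf
           else max(rpkm_nrh / rpkm_rh, rpkm_rh / rpkm_nrh)
  q < q_max && ratio > min_fold && max(rpkm_rh, rpkm_nrh) > min_rpkm
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

RHE_RAW <- "WHHDTGNNN(N)KCACGWH"

# Tiny two-exon fixture written as GFF3 text, used across io tests.
write_toy_gff3 <- function(path, strand = "+") {
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ttoy\tgene\t101\t400\t.\t%s\t.\tID=g1", strand),
    sprintf("chr1\ttoy\tmRNA\t101\t400\t.\t%s\t.\tID=g1.1;Parent=g1", strand),
    sprintf("chr1\ttoy\texon\t101\t200\t.\t%s\t.\tParent=g1.1", strand),
    sprintf("chr1\ttoy\texon\t301\t400\t.\t%s\t.\tParent=g1.1", strand),
    sprintf("chr1\ttoy\tCDS\t151\t200\t.\t%s\t.\tParent=g1.1", strand),
    sprintf("chr1\ttoy\tCDS\t301\t350\t.\t%s\t.\tParent=g1.1", strand)
  ), path)
  path
}

synth_gene_ids_for_test <- function(n) sprintf("G%05d", seq_len(n))

# root -> parent -> child chain with a 12-gene population; the child's 4
# annotated genes are exactly the 4-gene study set and the parent has no
# direct annotation of its own (used by enrichment and plot tests).
make_chain_dag <- function() {
  terms <- tibble::tibble(term_id = c("root", "par", "chi"),
                          name = c("r", "p", "c"))
  edges <- tibble::tibble(child = c("par", "chi"), parent = c("root", "par"))
  ann <- tibble::tibble(
    gene_id = c(paste0("g", 1:4), paste0("g", 1:12)),
    term_id = c(rep("chi", 4), rep("root", 12)))
  go_dag(terms, edges, ann)
}

# Independent full-scale scanner oracle: Biostrings degenerate matching with
# ambiguity codes interpreted in the pattern only (subject literal).
biostrings_scan_keys <- function(seq, raw) {
  subj <- Biostrings::DNAString(seq)
  keys <- character(0)
  for (letters in oracle_patterns(raw)) {
    pat <- Biostrings::DNAString(paste(letters, collapse = ""))
    L <- length(letters)
    fw <- Biostrings::matchPattern(pat, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    rv <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    if (length(fw) > 0L) {
      keys <- c(keys, paste("+", BiocGenerics::start(fw), L,
                            as.character(fw)))
    }
    if (length(rv) > 0L) {
      keys <- c(keys, paste("-", BiocGenerics::start(rv), L,
                            as.character(rv)))
    }
  }
  sort(keys)
}

# Half unit in the last printed decimal place of a number-as-printed.
half_ulp <- function(x_chr) {
  dec <- ifelse(grepl("\\.", x_chr),
                nchar(sub("^[^.]*\\.", "", x_chr)), 0L)
  10^(-dec) / 2
}
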