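#' Read transcript models from a GTF file
#'
#' Wraps `rtracklayer::import` and returns the exon-level `GRanges` plus
#' per-transcript metadata (gene id, biotype, union-exon length).
#'
#' @param path GTF file path.
#' @return List: `exons` (GRanges of exon records with `gene_id`,
#'   `transcript_id`, `gene_biotype`), `transcripts` (data.frame with
#'   `transcript_id`, `gene_id`, `gene_biotype`, `length`).
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0) stop("no exon records in ", path)
  by_tx <- S4Vectors::split(exons, exons$transcript_id)
  len <- sum(IRanges::width(IRanges::reduce(GenomicRanges::ranges(by_tx))))
  meta <- S4Vectors::mcols(exons)
  first <- !duplicated(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = exons$gene_id[first],
    gene_biotype = if (!is.null(meta$gene_biotype)) {
      exons$gene_biotype[first]
    } else NA_character_,
    stringsAsFactors = FALSE)
  transcripts$length <- as.integer(len[transcripts$transcript_id])
  list(exons = exons, transcripts = transcripts)
}

#' Classify lncRNA biotype by positional overlap with coding genes
#'
#' Precedence: antisense (exonic overlap with a coding gene on the opposite
#' strand) > sense_overlap (exonic overlap, same strand) > intronic (fully
#' inside a coding gene span, same strand, no exon overlap) > lincRNA
#' (no overlap with any coding gene span).
#'
#' @param lnc_exons GRanges of the lncRNA's exons (single transcript).
#' @param coding_exons GRanges of protein-coding exons (with `gene_id`).
#' @return One of `"lincRNA"`, `"antisense"`, `"intronic"`, `"sense_overlap"`.
#' @export
classify_biotype <- function(lnc_exons, coding_exons) {
  lnc_chr <- unique(as.character(GenomicRanges::seqnames(lnc_exons)))
  known <- unique(as.character(GenomicRanges::seqnames(coding_exons)))
  if (!all(lnc_chr %in% known)) {
    stop("unknown chromosome: ", paste(setdiff(lnc_chr, known), collapse = ", "))
  }
  gene_spans <- unlist(range(S4Vectors::split(coding_exons,
                                              coding_exons$gene_id)))
  exon_anti <- GenomicRanges::findOverlaps(
    lnc_exons, coding_exons, ignore.strand = TRUE)
  anti <- any(as.character(GenomicRanges::strand(lnc_exons))[
                S4Vectors::queryHits(exon_anti)] !=
              as.character(GenomicRanges::strand(coding_exons))[
                S4Vectors::subjectHits(exon_anti)])
  sense <- any(as.character(GenomicRanges::strand(lnc_exons))[
                 S4Vectors::queryHits(exon_anti)] ==
               as.character(GenomicRanges::strand(coding_exons))[
                 S4Vectors::subjectHits(exon_anti)])
  if (anti) return("antisense")
  if (sense) return("sense_overlap")
  within_span <- GenomicRanges::findOverlaps(
    range(lnc_exons), gene_spans, type = "within", ignore.strand = FALSE)
  if (length(within_span) > 0) return("intronic")
  any_span <- GenomicRanges::findOverlaps(range(lnc_exons), gene_spans,
                                          ignore.strand = TRUE)
  if (length(any_span) == 0) return("lincRNA")
  # overlaps a gene span but no exon and not nested: treat as lincRNA edge
  "lincRNA"
}

#' Coding-potential call from ORF and length rules
#'
#' Scans the three forward frames for ATG...stop open reading frames. A
#' transcript is `"noncoding"` when it is at least `min_length` nt long and
#' its longest ORF is under `max_orf_codons` codons; shorter transcripts are
#' excluded from the lncRNA universe (`"too_short"`), and transcripts with a
#' long ORF are `"coding_capable"`.
#'
#' @param seq Transcript sequence (ACGT or ACGU).
#' @param min_length Minimum lncRNA length in nt (default 200).
#' @param max_orf_codons ORF ceiling in codons, ATG through the codon before
#'   the stop (default 100, strict `<`).
#' @return List: `call` in `{"noncoding", "coding_capable", "too_short"}`,
#'   `longest_orf` in codons.
#' @export
coding_potential <- function(seq, min_length = 200, max_orf_codons = 100) {
  v <- .encode_rna(seq)  # validates the alphabet
  n <- length(v)
  longest <- .longest_orf_codons(toupper(chartr("Uu", "Tt", seq)))
  call <- if (n < min_length) {
    "too_short"
  } else if (longest < max_orf_codons) {
    "noncoding"
  } else {
    "coding_capable"
  }
  list(call = call, longest_orf = longest)
}

# longest ATG..stop ORF over the 3 forward frames, in codons (excl. stop)
.longest_orf_codons <- function(dna) {
  v <- strsplit(dna, "")[[1]]
  n <- length(v)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- vapply(starts, function(i) paste(v[i:(i + 2)], collapse = ""),
                     character(1))
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at) && codons[k] == "ATG") open_at <- k
      if (!is.na(open_at) && codons[k] %in% stops) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Infer lncRNA cis targets by co-localization and co-expression
#'
#' Candidate targets are coding genes whose span lies within `window` nt of
#' the lncRNA locus. Each candidate is scored by the Pearson correlation of
#' lncRNA and mRNA expression across shared samples; pairs with `r > r_min`
#' are retained as co-expressed cis pairs, and flagged `is_true_target` when
#' the mRNA also belongs to the nodulation-regulated mRNA set (the
#' intersection rule).
#'
#' @param lnc_expr Expression matrix, lncRNAs x samples (FPKM).
#' @param mrna_expr Expression matrix, mRNAs x samples (FPKM).
#' @param lnc_loci GRanges, one range per lncRNA (names = lncRNA ids).
#' @param gene_loci GRanges, one span per coding gene (names = gene ids).
#' @param nr_mrna_set Character vector of NR-mRNA ids.
#' @param window Cis window in nt (default 1e5).
#' @param r_min Correlation threshold, strict `>` (default 0.6).
#' @param absolute Use |r| instead of r (default FALSE).
#' @return data.frame: `lncrna`, `mrna`, `relation`, `distance`, `pearson_r`,
#'   `in_nr_set`, `is_true_target`.
#' @export
infer_targets <- function(lnc_expr, mrna_expr, lnc_loci, gene_loci,
                          nr_mrna_set = character(0), window = 1e5,
                          r_min = 0.6, absolute = FALSE) {
  shared <- intersect(colnames(lnc_expr), colnames(mrna_expr))
  if (length(shared) < 4) stop("need >= 4 shared samples for correlation")
  lnc_expr <- lnc_expr[, shared, drop = FALSE]
  mrna_expr <- mrna_expr[, shared, drop = FALSE]
  hits <- GenomicRanges::findOverlaps(
    lnc_loci, gene_loci, maxgap = window, ignore.strand = TRUE)
  out <- list()
  for (k in seq_along(hits)) {
    l_id <- names(lnc_loci)[S4Vectors::queryHits(hits)[k]]
    g_id <- names(gene_loci)[S4Vectors::subjectHits(hits)[k]]
    if (!l_id %in% rownames(lnc_expr) || !g_id %in% rownames(mrna_expr)) next
    x <- lnc_expr[l_id, ]; y <- mrna_expr[g_id, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    score <- if (absolute) abs(r) else r
    if (score <= r_min) next
    dist <- GenomicRanges::distance(
      lnc_loci[S4Vectors::queryHits(hits)[k]],
      gene_loci[S4Vectors::subjectHits(hits)[k]], ignore.strand = TRUE)
    out[[length(out) + 1]] <- data.frame(
      lncrna = l_id, mrna = g_id, relation = "cis",
      distance = as.integer(dist), pearson_r = r,
      in_nr_set = g_id %in% nr_mrna_set,
      is_true_target = g_id %in% nr_mrna_set,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(lncrna = character(0), mrna = character(0),
                      relation = character(0), distance = integer(0),
                      pearson_r = numeric(0), in_nr_set = logical(0),
                      is_true_target = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
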