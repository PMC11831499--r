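#' Default pipeline parameters
#'
#' All stage thresholds with the analysis defaults: per-class NR thresholds,
#' detectability rule, cis window and correlation gates, MRE penalty cutoff,
#' confidence and shared-site gates, and module parameters.
#'
#' @return Named list of parameters.
#' @export
pipeline_params <- function() {
  list(
    min_fpkm = 0.5, min_fraction = 0.10,
    thresholds = list(mRNA = class_thresholds("mRNA"),
                      lncRNA = class_thresholds("lncRNA"),
                      miRNA = class_thresholds("miRNA"),
                      circRNA = class_thresholds("circRNA")),
    cis_window = 1e5, r_min = 0.6,
    mre_cutoff = 4.0, min_confidence = 0.5,
    cerna_q_max = 0.05, cerna_r_pos_min = 0.6,
    min_module_size = 30, merge_height = 0.25, beta = NULL,
    trait_r_min = 0.8,
    focal_tissue = "root")
}

#' Run the full nodulation ceRNA analysis on a fixture directory
#'
#' Reads the fixture written by [write_fixture()] (or equivalently formatted
#' real data), then runs: normalization (FPKM/TPM) -> detectability filter ->
#' per-tissue rhizobia-vs-mock differential expression in the wild type ->
#' NR classification per class -> mutant-vs-wild-type (NARK) differential
#' expression -> lncRNA co-expression modules and module-trait correlation ->
#' NNR union -> lncRNA cis-target inference -> MRE scanning and precursor
#' screening -> ceRNA pair filtering, shared-MRE testing, and network
#' assembly for the focal tissue. Every stage writes its table under `outdir`
#' and is recorded in `manifest.json` with parameter and output checksums;
#' with `resume = TRUE` a stage whose recorded input/parameter state is
#' unchanged is skipped and its outputs are reused.
#'
#' @param fixture_dir Directory containing the input files.
#' @param outdir Output directory.
#' @param params See [pipeline_params()].
#' @param resume Skip stages whose inputs are unchanged (default FALSE).
#' @return List with the main results and the manifest.
#' @export
run_pipeline <- function(fixture_dir, outdir, params = pipeline_params(),
                         resume = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.json")
  inputs <- list.files(fixture_dir, full.names = TRUE)
  state <- list(inputs = unname(tools::md5sum(inputs)),
                params = params)
  state_hash <- .hash_obj(state)
  if (resume && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(old$state_hash, state_hash)) {
      message("pipeline: all stages up to date, skipping")
      res <- .read_pipeline_outputs(outdir)
      res$manifest <- old
      res$resumed <- TRUE
      return(res)
    }
  }
  stages <- list()
  log <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  # --- stage: read inputs ---
  log("read", paste("loading fixture from", fixture_dir))
  samples <- utils::read.delim(file.path(fixture_dir, "sample_sheet.tsv"),
                               stringsAsFactors = FALSE)
  counts <- list()
  for (cl in c("mRNA", "lncRNA", "miRNA", "circRNA")) {
    f <- file.path(fixture_dir, sprintf("counts_%s.tsv", tolower(cl)))
    if (file.exists(f)) counts[[cl]] <- read_count_tsv(f)
  }
  models <- read_gtf_models(file.path(fixture_dir, "models.gtf"))
  tx_seqs <- .read_fasta(file.path(fixture_dir, "transcripts.fa"))
  mirna_seqs <- .read_fasta(file.path(fixture_dir, "mirna_mature.fa"))
  precursor_seqs <- .read_fasta(file.path(fixture_dir, "mirna_precursor.fa"))
  gene_len <- stats::setNames(models$transcripts$length,
                              models$transcripts$gene_id)
  stages$read <- length(counts)

  # --- stage: normalize ---
  log("normalize", "FPKM (mRNA/lncRNA), TPM (miRNA/circRNA)")
  expr <- list()
  for (cl in names(counts)) {
    expr[[cl]] <- if (cl %in% c("mRNA", "lncRNA")) {
      normalize_counts(counts[[cl]], "fpkm",
                       lengths = gene_len[rownames(counts[[cl]])])
    } else {
      normalize_counts(counts[[cl]], "mirna_tpm")
    }
    .write_tsv_mat(expr[[cl]], file.path(outdir,
                   sprintf("expr_%s.tsv", tolower(cl))))
  }

  # --- stage: detectability ---
  detected <- lapply(expr, detectable, min_value = params$min_fpkm,
                     min_fraction = params$min_fraction)
  for (cl in names(detected)) {
    log("detect", sprintf("%s: %d / %d detectable", cl,
                          length(detected[[cl]]), nrow(counts[[cl]])))
    counts[[cl]] <- counts[[cl]][detected[[cl]], , drop = FALSE]
    expr[[cl]] <- expr[[cl]][detected[[cl]], , drop = FALSE]
  }

  # --- stage: NR differential expression (WT, rhizobia vs mock, per tissue)
  tissues <- unique(samples$tissue)
  de_nr <- list(); nr_sets <- list()
  for (cl in names(counts)) {
    for (tis in tissues) {
      sel <- samples$genotype == "WT" & samples$tissue == tis
      de <- .de_two_group(counts[[cl]][, samples$sample[sel], drop = FALSE],
                          factor(samples$treatment[sel],
                                 levels = c("mock", "rhizobia")))
      de$rna_class <- cl; de$contrast <- paste0(tis, ":rhizobia-vs-mock")
      de_nr[[paste(cl, tis, sep = ".")]] <- de
      nr_sets[[cl]][[tis]] <- classify_regulated(de, params$thresholds[[cl]])
      utils::write.table(de, file.path(outdir,
        sprintf("de_nr_%s_%s.tsv", tolower(cl), tis)), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    log("de_nr", sprintf("%s: %s NR features per tissue", cl,
        paste(vapply(nr_sets[[cl]], function(s) {
          length(s$up) + length(s$down)
        }, 1L), collapse = "/")))
  }

  # --- stage: tissue specificity of NR sets ---
  nr_spec <- lapply(nr_sets, function(per_tissue) {
    tissue_specificity(lapply(per_tissue, function(s) c(s$up, s$down)))
  })

  # --- stage: NARK differential expression (mutant vs WT per tissue x trt)
  de_nark <- list(); nark_sets <- list()
  for (cl in names(counts)) {
    ups <- character(0); downs <- character(0)
    for (tis in tissues) {
      for (trt in unique(samples$treatment)) {
        sel <- samples$tissue == tis & samples$treatment == trt
        de <- .de_two_group(counts[[cl]][, samples$sample[sel], drop = FALSE],
                            factor(samples$genotype[sel],
                                   levels = c("WT", "mutant")))
        de$rna_class <- cl
        de$contrast <- paste0(tis, ":", trt, ":mutant-vs-WT")
        de_nark[[paste(cl, tis, trt, sep = ".")]] <- de
        s <- classify_regulated(de, params$thresholds[[cl]])
        ups <- union(ups, s$up); downs <- union(downs, s$down)
      }
    }
    nark_sets[[cl]] <- list(up = setdiff(ups, downs),
                            down = setdiff(downs, ups))
    log("de_nark", sprintf("%s: %d NARK features", cl,
                           length(ups) + length(downs)))
  }

  # --- stage: lncRNA co-expression modules ---
  lnc_log <- t(log2(expr$lncRNA + 0.001))
  beta_sel <- if (is.null(params$beta)) {
    select_soft_power(lnc_log)
  } else {
    list(beta = params$beta, warning = FALSE, fit = NULL)
  }
  mods <- detect_modules(lnc_log, beta_sel$beta,
                         min_size = params$min_module_size,
                         merge_height = params$merge_height)
  traits <- data.frame(
    genotype = as.numeric(samples$genotype == "mutant"),
    rhizobia = as.numeric(samples$treatment == "rhizobia"),
    row.names = samples$sample)
  mtc <- module_trait_correlation(mods$eigengenes, traits)
  module_members <- trait_module_members(mods$labels, mtc, "genotype",
                                         r_min = params$trait_r_min)
  log("modules", sprintf("beta = %d, %d modules, %d genotype-module members",
                         beta_sel$beta, ncol(mods$eigengenes),
                         length(module_members)))
  utils::write.table(
    data.frame(feature = names(mods$labels), module = mods$labels),
    file.path(outdir, "modules_lncrna.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # --- stage: NNR union ---
  nnr <- list()
  for (cl in names(counts)) {
    mod_arm <- if (cl == "lncRNA") module_members else character(0)
    nnr[[cl]] <- define_nnr(nark_sets[[cl]], mod_arm)
    utils::write.table(nnr[[cl]], file.path(outdir,
      sprintf("nnr_%s.tsv", tolower(cl))), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  # --- stage: lncRNA cis targets ---
  loci <- .gene_loci(models)
  nr_mrna_all <- unique(unlist(lapply(nr_sets$mRNA, function(s) {
    c(s$up, s$down)
  })))
  focal <- samples$tissue == params$focal_tissue
  # co-expression gates work on log2(abundance + 1): correlation of
  # multiplicative expression signals is linear on the log scale
  log_expr <- lapply(expr, function(m) log2(m + 1))
  lnc_targets <- infer_targets(
    log_expr$lncRNA[, samples$sample[focal], drop = FALSE],
    log_expr$mRNA[, samples$sample[focal], drop = FALSE],
    loci$lncRNA, loci$mRNA, nr_mrna_set = nr_mrna_all,
    window = params$cis_window, r_min = params$r_min)
  utils::write.table(lnc_targets, file.path(outdir, "lncrna_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("lnc_targets", sprintf("%d cis pairs, %d true targets",
                             nrow(lnc_targets), sum(lnc_targets$is_true_target)))

  # --- stage: MRE scanning ---
  lnc_ids <- intersect(names(tx_seqs), rownames(expr$lncRNA))
  mrna_ids <- intersect(names(tx_seqs), rownames(expr$mRNA))
  lnc_sites <- scan_all_mres(mirna_seqs, tx_seqs[lnc_ids],
                             cutoff = params$mre_cutoff)
  mrna_sites <- scan_all_mres(mirna_seqs, tx_seqs[mrna_ids],
                              cutoff = params$mre_cutoff)
  mimic <- precursor_mimic_table(tx_seqs[lnc_ids], precursor_seqs)
  utils::write.table(rbind(lnc_sites, mrna_sites),
                     file.path(outdir, "mre_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log("mre_scan", sprintf("%d lncRNA sites, %d mRNA sites",
                          nrow(lnc_sites), nrow(mrna_sites)))

  # --- stage: ceRNA network (all samples of the focal tissue) ---
  wt_focal <- samples$sample[focal]
  pairs <- lncrna_mirna_pairs(
    lnc_sites, mimic,
    nr_sets$lncRNA[[params$focal_tissue]],
    nr_sets$miRNA[[params$focal_tissue]],
    log_expr$lncRNA[, wt_focal, drop = FALSE],
    log_expr$miRNA[, wt_focal, drop = FALSE],
    min_confidence = params$min_confidence)
  lnc_mir_sets <- mirna_sets_from_sites(lnc_sites, params$min_confidence)
  mrna_mir_sets <- mirna_sets_from_sites(mrna_sites, params$min_confidence)
  universe <- unique(c(unlist(lnc_mir_sets), unlist(mrna_mir_sets)))
  shared <- shared_mre_test(lnc_mir_sets, mrna_mir_sets, universe)
  net <- assemble_network(
    pairs, mrna_sites, shared,
    log_expr$lncRNA[, wt_focal, drop = FALSE],
    log_expr$mRNA[, wt_focal, drop = FALSE],
    de_dirs = list(lncRNA = nr_sets$lncRNA[[params$focal_tissue]],
                   miRNA = nr_sets$miRNA[[params$focal_tissue]],
                   mRNA = nr_sets$mRNA[[params$focal_tissue]]),
    q_max = params$cerna_q_max, r_pos_min = params$cerna_r_pos_min,
    min_confidence = params$min_confidence)
  utils::write.table(net$triplets, file.path(outdir, "cerna_triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(net$network,
                 graphml_path = file.path(outdir, "cerna_network.graphml"),
                 sif_path = file.path(outdir, "cerna_network.sif"))
  log("cerna", sprintf("%d candidate pairs, %d triplets retained",
                       nrow(pairs), nrow(net$triplets)))

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    state_hash = state_hash,
    stages = c("read", "normalize", "detect", "de_nr", "tissue_specificity",
               "de_nark", "modules", "nnr", "lnc_targets", "mre_scan",
               "cerna"),
    params = params,
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(expr = expr, detected = detected, de_nr = de_nr, nr_sets = nr_sets,
       nr_specificity = nr_spec, nark_sets = nark_sets, modules = mods,
       beta = beta_sel, module_trait = mtc, nnr = nnr,
       lnc_targets = lnc_targets, lnc_sites = lnc_sites,
       mrna_sites = mrna_sites, pairs = pairs, shared = shared,
       triplets = net$triplets, network = net$network, manifest = manifest,
       resumed = FALSE)
}

# two-group DE: scaling factors -> common dispersion -> exact test -> BH
.de_two_group <- function(counts, group) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0) {
    return(data.frame(feature = character(0), log2fc = numeric(0),
                      pvalue = numeric(0), qvalue = numeric(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  f <- scaling_factors(counts)
  phi <- estimate_dispersion(counts, group, factors = f)
  de <- nb_test(counts, group, phi, factors = f)
  de$qvalue <- bh_adjust(de$pvalue)
  de
}

.gene_loci <- function(models) {
  tx <- models$transcripts
  spans <- unlist(range(S4Vectors::split(models$exons,
                                         models$exons$gene_id)))
  biotype <- stats::setNames(tx$gene_biotype, tx$gene_id)
  out <- list()
  for (cl in c("mRNA", "lncRNA")) {
    bt <- if (cl == "mRNA") "protein_coding" else "lncRNA"
    ids <- names(spans)[biotype[names(spans)] == bt]
    out[[cl]] <- spans[ids]
  }
  out
}

.read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

.write_tsv_mat <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
             f)
  unname(tools::md5sum(f))
}

.read_pipeline_outputs <- function(outdir) {
  read_if <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
  }
  list(triplets = read_if("cerna_triplets.tsv"),
       lnc_targets = read_if("lncrna_targets.tsv"))
}
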