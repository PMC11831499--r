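#' Simulation configuration for the nodulation study design
#'
#' Defaults emulate the study design: 2 genotypes x 3 tissues x 2 treatments
#' x 3 replicates = 36 samples, with negative-binomial counts, planted
#' treatment (nodulation) effects, a genotype-driven lncRNA co-expression
#' module, and planted ceRNA triplets. Each planted decoy-target pair carries
#' `mirnas_per_pair` core miRNAs (default 2), the typical multi-site ceRNA
#' configuration, so `n_planted_triplets` must be a multiple of
#' `mirnas_per_pair`.
#'
#' @param n_mrna,n_lncrna,n_mirna,n_circrna Feature counts per RNA class.
#' @param genome_length Synthetic chromosome length (nt).
#' @param baseline_mean Expected baseline count per feature.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param de_effect Planted |log2 fold change| for NR features.
#' @param n_planted_de Named vector: planted NR features per class (split
#'   evenly over the 3 tissues, alternating up/down).
#' @param n_planted_nark Named vector: planted genotype-responsive (DE-NARK)
#'   features per class.
#' @param n_planted_triplets Planted ceRNA triplets.
#' @param mirnas_per_pair Core miRNAs per planted decoy-target pair.
#' @param n_planted_modules Planted lncRNA co-expression modules (module 1 is
#'   genotype-driven).
#' @param module_size Members per planted module.
#' @param mre_cutoff Scanner penalty cutoff used for rejection sampling.
#' @param seed Master seed; named substreams are derived from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 300, n_lncrna = 100, n_mirna = 20,
                       n_circrna = 10, genome_length = 4e6,
                       baseline_mean = 100, dispersion = 0.1, de_effect = 2,
                       n_planted_de = c(mRNA = 30, lncRNA = 15, miRNA = 6,
                                        circRNA = 4),
                       n_planted_nark = c(mRNA = 20, lncRNA = 10, miRNA = 4,
                                          circRNA = 2),
                       n_planted_triplets = 10, mirnas_per_pair = 2,
                       n_planted_modules = 1, module_size = 40, seed = 42,
                       mre_cutoff = 4.0) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_circrna = n_circrna, genome_length = genome_length,
              baseline_mean = baseline_mean, dispersion = dispersion,
              de_effect = de_effect, n_planted_de = n_planted_de,
              n_planted_nark = n_planted_nark,
              n_planted_triplets = n_planted_triplets,
              mirnas_per_pair = mirnas_per_pair,
              n_planted_modules = n_planted_modules,
              module_size = module_size, seed = seed,
              mre_cutoff = mre_cutoff,
              design = study_design())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' The 2 x 3 x 2 x 3 study design
#'
#' @return data.frame: `sample`, `genotype`, `tissue`, `treatment`,
#'   `replicate` (36 rows).
#' @export
study_design <- function() {
  d <- expand.grid(replicate = 1:3, treatment = c("mock", "rhizobia"),
                   tissue = c("root", "cotyledon", "leaf"),
                   genotype = c("WT", "mutant"),
                   stringsAsFactors = FALSE)
  d <- d[, c("genotype", "tissue", "treatment", "replicate")]
  d$sample <- paste(d$genotype, d$tissue, d$treatment, d$replicate, sep = "_")
  d[, c("sample", "genotype", "tissue", "treatment", "replicate")]
}

#' Validate a simulation configuration
#'
#' Checks count/dispersion invariants, triplet and module feasibility, and
#' replication in the design; errors name the conflicting fields.
#'
#' @param cfg A [sim_config()].
#' @return The config, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_mrna >= 0, cfg$n_lncrna >= 0, cfg$n_mirna >= 0,
            cfg$n_circrna >= 0, cfg$dispersion >= 0, cfg$de_effect >= 0,
            cfg$genome_length > 0)
  n_pairs <- cfg$n_planted_triplets / cfg$mirnas_per_pair
  if (cfg$n_planted_triplets %% cfg$mirnas_per_pair != 0) {
    stop("n_planted_triplets must be a multiple of mirnas_per_pair")
  }
  if (cfg$n_planted_triplets > 0 &&
      (cfg$n_mrna < n_pairs || cfg$n_lncrna < n_pairs ||
       cfg$n_mirna < cfg$n_planted_triplets)) {
    stop("n_planted_triplets requires n_mrna, n_lncrna >= ",
         n_pairs, " and n_mirna >= ", cfg$n_planted_triplets,
         " (conflicting fields: n_planted_triplets, n_mrna, n_lncrna, n_mirna)")
  }
  if (cfg$n_planted_modules > 0 &&
      cfg$n_lncrna < n_pairs + cfg$n_planted_modules * cfg$module_size) {
    stop("planted modules need more lncRNAs: n_lncrna too small for ",
         "n_planted_modules x module_size (conflicting fields: n_lncrna, ",
         "n_planted_modules, module_size)")
  }
  reps <- table(interaction(cfg$design$genotype, cfg$design$tissue,
                            cfg$design$treatment))
  if (any(reps < 2)) stop("design needs >= 2 replicates per condition")
  invisible(cfg)
}

# substream seed derived from the master seed and a stage name
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + h * 1009L) %% .Machine$integer.max
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the ground-truth layout for a simulation
#'
#' Draws miRNA, precursor, mRNA and lncRNA sequences (rejection-sampled so no
#' transcript carries a chance binding site at penalty <= `mre_cutoff` for any
#' miRNA), plants exact-complement MREs for every triplet's core miRNAs on
#' both decoy and target (plus one background MRE per non-core miRNA so the
#' miRNA universe is fully represented), lays out loci on a synthetic
#' chromosome with triplet decoys adjacent to their targets, and assigns
#' planted NR / NARK features and module memberships.
#'
#' @param config A [sim_config()].
#' @return List of class `truth_set`.
#' @export
generate_truth <- function(config) {
  validate_sim_config(config)
  ids <- list(
    mRNA = sprintf("MRNA_%04d", seq_len(config$n_mrna)),
    lncRNA = sprintf("LNC_%04d", seq_len(config$n_lncrna)),
    miRNA = sprintf("MIR_%04d", seq_len(config$n_mirna)),
    circRNA = sprintf("CIRC_%04d", seq_len(config$n_circrna)))

  # --- sequences ---
  set.seed(.substream_seed(config$seed, "sequences"))
  mirna_seq <- stats::setNames(
    vapply(seq_len(config$n_mirna), function(i) .random_dna(21), ""),
    ids$miRNA)
  mirna_seq <- chartr("T", "U", mirna_seq)
  precursor_seq <- stats::setNames(vapply(seq_len(config$n_mirna), function(i) {
    flank5 <- .random_dna(40); flank3 <- .random_dna(60)
    paste0(flank5, chartr("U", "T", mirna_seq[i]), flank3)
  }, ""), ids$miRNA)
  draw_clean <- function(len) {
    repeat {
      s <- .random_dna(len)
      if (.no_mre(s, mirna_seq, config$mre_cutoff)) return(s)
    }
  }
  mrna_len <- sample(500:1200, config$n_mrna, replace = TRUE)
  lnc_len <- sample(300:800, config$n_lncrna, replace = TRUE)
  mrna_seq <- stats::setNames(vapply(mrna_len, draw_clean, ""), ids$mRNA)
  lnc_seq <- stats::setNames(vapply(lnc_len, draw_clean, ""), ids$lncRNA)

  # --- triplets and MRE planting ---
  set.seed(.substream_seed(config$seed, "planting"))
  n_pairs <- config$n_planted_triplets / config$mirnas_per_pair
  triplets <- NULL
  mre_truth <- NULL
  if (config$n_planted_triplets > 0) {
    pair_lnc <- ids$lncRNA[seq_len(n_pairs)]
    pair_mrna <- ids$mRNA[seq_len(n_pairs)]
    core_mirna <- ids$miRNA[seq_len(config$n_planted_triplets)]
    # decoy/target direction alternates by pair (both response signs occur);
    # cores always move opposite to their decoys
    pair_dir <- rep(c("down", "up"), length.out = n_pairs)
    triplets <- data.frame(
      lncrna = rep(pair_lnc, each = config$mirnas_per_pair),
      mirna = core_mirna,
      mrna = rep(pair_mrna, each = config$mirnas_per_pair),
      tissue = "root",
      decoy_direction = rep(pair_dir, each = config$mirnas_per_pair),
      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(triplets))) {
      for (side in c("lncrna", "mrna")) {
        tid <- triplets[[side]][k]
        seqs <- if (side == "lncrna") lnc_seq else mrna_seq
        planted <- .plant_mre(seqs[[tid]], mirna_seq[[triplets$mirna[k]]],
                              mirna_seq, config$mre_cutoff)
        if (side == "lncrna") lnc_seq[[tid]] <- planted$seq
        else mrna_seq[[tid]] <- planted$seq
        mre_truth <- rbind(mre_truth, data.frame(
          mirna = triplets$mirna[k], target = tid, start = planted$start,
          stringsAsFactors = FALSE))
      }
    }
    # background MREs: every non-core miRNA hits one non-triplet mRNA so the
    # miRNA universe (>= 1 MRE anywhere) covers all simulated miRNAs
    bg_mirna <- setdiff(ids$miRNA, core_mirna)
    bg_mrna <- setdiff(ids$mRNA, pair_mrna)[seq_along(bg_mirna)]
    for (k in seq_along(bg_mirna)) {
      planted <- .plant_mre(mrna_seq[[bg_mrna[k]]], mirna_seq[[bg_mirna[k]]],
                            mirna_seq, config$mre_cutoff)
      mrna_seq[[bg_mrna[k]]] <- planted$seq
      mre_truth <- rbind(mre_truth, data.frame(
        mirna = bg_mirna[k], target = bg_mrna[k], start = planted$start,
        stringsAsFactors = FALSE))
    }
  }

  # --- genomic layout: 8 kb slots on one chromosome; decoys next to targets
  slot <- 8000L
  n_loci <- config$n_mrna + config$n_lncrna
  if (n_loci * slot > config$genome_length) {
    stop("genome_length too small for ", n_loci, " loci at ", slot, " nt each")
  }
  order_ids <- character(n_loci)
  pos <- 1L
  used_lnc <- character(0)
  for (i in seq_len(config$n_mrna)) {
    order_ids[pos] <- ids$mRNA[i]; pos <- pos + 1L
    if (!is.null(triplets) && ids$mRNA[i] %in% triplets$mrna) {
      l <- unique(triplets$lncrna[triplets$mrna == ids$mRNA[i]])
      order_ids[pos] <- l; pos <- pos + 1L
      used_lnc <- c(used_lnc, l)
    }
  }
  rest <- setdiff(ids$lncRNA, used_lnc)
  order_ids[pos:(pos + length(rest) - 1L)] <- rest
  all_len <- c(stats::setNames(mrna_len, ids$mRNA),
               stats::setNames(lnc_len, ids$lncRNA))
  loci <- data.frame(
    id = order_ids,
    class = ifelse(order_ids %in% ids$mRNA, "mRNA", "lncRNA"),
    chrom = "chr1",
    start = (seq_len(n_loci) - 1L) * slot + 1L,
    strand = rep(c("+", "-"), length.out = n_loci),
    stringsAsFactors = FALSE)
  loci$end <- loci$start + all_len[loci$id] - 1L
  loci$length <- all_len[loci$id]

  # --- planted NR (treatment) and NARK (genotype) features ---
  reserved <- c(if (!is.null(triplets)) {
    c(triplets$lncrna, triplets$mrna, triplets$mirna)
  }, character(0))
  tissues <- c("root", "cotyledon", "leaf")
  planted_nr <- NULL
  planted_nark <- NULL
  pool <- lapply(ids, function(x) setdiff(x, reserved))
  for (cl in names(config$n_planted_de)) {
    n_de <- min(config$n_planted_de[[cl]], length(pool[[cl]]))
    if (n_de == 0) next
    feats <- pool[[cl]][seq_len(n_de)]
    pool[[cl]] <- setdiff(pool[[cl]], feats)
    planted_nr <- rbind(planted_nr, data.frame(
      feature = feats, class = cl,
      tissue = rep(tissues, length.out = n_de),
      direction = rep(c("up", "down"), length.out = n_de),
      stringsAsFactors = FALSE))
  }
  for (cl in names(config$n_planted_nark)) {
    n_nk <- min(config$n_planted_nark[[cl]], length(pool[[cl]]))
    if (n_nk == 0) next
    feats <- pool[[cl]][seq_len(n_nk)]
    pool[[cl]] <- setdiff(pool[[cl]], feats)
    planted_nark <- rbind(planted_nark, data.frame(
      feature = feats, class = cl,
      tissue = rep(tissues, length.out = n_nk),
      direction = rep(c("up", "down"), length.out = n_nk),
      stringsAsFactors = FALSE))
  }
  # triplet members are NR in root: decoy and target share the pair's
  # direction, cores take the opposite one
  if (!is.null(triplets)) {
    first_l <- !duplicated(triplets$lncrna)
    first_m <- !duplicated(triplets$mrna)
    planted_nr <- rbind(planted_nr,
      data.frame(feature = triplets$lncrna[first_l], class = "lncRNA",
                 tissue = "root", direction = triplets$decoy_direction[first_l],
                 stringsAsFactors = FALSE),
      data.frame(feature = triplets$mrna[first_m], class = "mRNA",
                 tissue = "root", direction = triplets$decoy_direction[first_m],
                 stringsAsFactors = FALSE),
      data.frame(feature = triplets$mirna, class = "miRNA",
                 tissue = "root",
                 direction = ifelse(triplets$decoy_direction == "down",
                                    "up", "down"),
                 stringsAsFactors = FALSE))
  }

  # --- planted lncRNA modules (module 1 genotype-driven) ---
  modules <- NULL
  if (config$n_planted_modules > 0) {
    for (m in seq_len(config$n_planted_modules)) {
      n_mem <- min(config$module_size, length(pool$lncRNA))
      if (n_mem == 0) break
      feats <- pool$lncRNA[seq_len(n_mem)]
      pool$lncRNA <- setdiff(pool$lncRNA, feats)
      modules <- rbind(modules, data.frame(
        feature = feats, module = m,
        loading = stats::runif(n_mem, 0.8, 1.2),
        stringsAsFactors = FALSE))
    }
  }

  truth <- list(ids = ids, mirna_seq = mirna_seq,
                precursor_seq = precursor_seq, mrna_seq = mrna_seq,
                lnc_seq = lnc_seq, loci = loci, triplets = triplets,
                mre_truth = mre_truth, planted_nr = planted_nr,
                planted_nark = planted_nark, modules = modules,
                lengths = list(mRNA = stats::setNames(mrna_len, ids$mRNA),
                               lncRNA = stats::setNames(lnc_len, ids$lncRNA),
                               miRNA = stats::setNames(
                                 rep(21L, config$n_mirna), ids$miRNA),
                               circRNA = stats::setNames(
                                 sample(300:900, config$n_circrna,
                                        replace = TRUE), ids$circRNA)),
                config = config)
  class(truth) <- "truth_set"
  truth
}

# TRUE when no miRNA has a site at or under the cutoff on this sequence
.no_mre <- function(seq, mirna_seqs, cutoff) {
  for (m in mirna_seqs) {
    if (nrow(scan_mres(m, seq, cutoff = cutoff)) > 0) return(FALSE)
  }
  TRUE
}

# insert the exact reverse complement of the miRNA at a random position,
# redrawing until the sequence has exactly the intended extra site set
.plant_mre <- function(seq, mirna, all_mirnas, cutoff, max_tries = 50) {
  site <- chartr("U", "T", reverse_complement(mirna))
  L <- nchar(site)
  n <- nchar(seq)
  before <- sum(vapply(all_mirnas, function(m) {
    nrow(scan_mres(m, seq, cutoff = cutoff))
  }, numeric(1)))
  for (try in seq_len(max_tries)) {
    start <- sample.int(n - L + 1, 1)
    cand <- paste0(substr(seq, 1, start - 1), site, substr(seq, start + L, n))
    after <- sum(vapply(all_mirnas, function(m) {
      nrow(scan_mres(m, cand, cutoff = cutoff))
    }, numeric(1)))
    if (after == before + 1) {
      return(list(seq = cand, start = start - 1L))
    }
  }
  stop("could not plant MRE without creating spurious sites")
}

#' Simulate negative-binomial count matrices from a truth set
#'
#' Counts are NB(mean = condition mean x sample depth factor, dispersion phi);
#' depth factors are log-uniform in [0.5, 2] per sample and class. Planted NR
#' features split `de_effect` symmetrically between mock and rhizobia in their
#' planted tissue (both genotypes); NARK features do the same between
#' genotypes; triplet cores move opposite to their decoys; lncRNA module
#' members follow a genotype latent factor with per-feature loadings.
#'
#' @param truth A [generate_truth()] result.
#' @param config The same [sim_config()].
#' @return List: `counts` (one matrix per class), `mu` (expected means),
#'   `depth` (per class depth factors), `design`.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  design <- config$design
  n <- nrow(design)
  set.seed(.substream_seed(config$seed, "counts"))
  classes <- c("mRNA", "lncRNA", "miRNA", "circRNA")
  counts <- list(); mu_list <- list(); depth_list <- list()
  for (cl in classes) {
    feats <- truth$ids[[cl]]
    if (length(feats) == 0) {
      counts[[cl]] <- matrix(0L, 0, n, dimnames = list(NULL, design$sample))
      next
    }
    lfc <- matrix(0, length(feats), n,
                  dimnames = list(feats, design$sample))
    pn <- truth$planted_nr
    if (!is.null(pn)) {
      for (k in which(pn$class == cl)) {
        j <- design$tissue == pn$tissue[k] & design$treatment == "rhizobia"
        jm <- design$tissue == pn$tissue[k] & design$treatment == "mock"
        s <- if (pn$direction[k] == "up") 1 else -1
        lfc[pn$feature[k], j] <- lfc[pn$feature[k], j] + s * config$de_effect / 2
        lfc[pn$feature[k], jm] <- lfc[pn$feature[k], jm] - s * config$de_effect / 2
      }
    }
    pk <- truth$planted_nark
    if (!is.null(pk)) {
      for (k in which(pk$class == cl)) {
        j <- design$tissue == pk$tissue[k] & design$genotype == "mutant"
        jw <- design$tissue == pk$tissue[k] & design$genotype == "WT"
        s <- if (pk$direction[k] == "up") 1 else -1
        lfc[pk$feature[k], j] <- lfc[pk$feature[k], j] + s * config$de_effect / 2
        lfc[pk$feature[k], jw] <- lfc[pk$feature[k], jw] - s * config$de_effect / 2
      }
    }
    if (cl == "lncRNA" && !is.null(truth$modules)) {
      latent <- ifelse(design$genotype == "mutant", -1, 1)
      for (k in seq_len(nrow(truth$modules))) {
        f <- truth$modules$feature[k]
        load <- truth$modules$loading[k]
        if (truth$modules$module[k] == 1) {
          lfc[f, ] <- lfc[f, ] + load * latent
        } else {
          set.seed(.substream_seed(config$seed,
                                   paste0("module_latent_",
                                          truth$modules$module[k])))
          lat_m <- sample(c(-1, 1), n, replace = TRUE)
          lfc[f, ] <- lfc[f, ] + load * lat_m
        }
      }
    }
    base <- config$baseline_mean
    depth <- exp(stats::runif(n, log(0.5), log(2)))
    mu <- base * 2^lfc
    mu <- sweep(mu, 2, depth, "*")
    phi <- config$dispersion
    cnt <- if (phi == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), size = 1 / phi, mu = mu), nrow(mu))
    }
    dimnames(cnt) <- dimnames(mu)
    counts[[cl]] <- cnt
    mu_list[[cl]] <- mu
    depth_list[[cl]] <- stats::setNames(depth, design$sample)
  }
  list(counts = counts, mu = mu_list, depth = depth_list, design = design)
}

#' Write a synthetic fixture to disk
#'
#' Emits a GTF (gene/transcript/exon records for mRNA and lncRNA loci),
#' transcript FASTA, mature miRNA and precursor FASTA, one count TSV per
#' class, the sample sheet, truth TSVs (planted NR/NARK features, triplets,
#' MRE coordinates, module membership), and a manifest with md5 checksums.
#'
#' @param truth A [generate_truth()] result.
#' @param sim A [simulate_counts()] result.
#' @param outdir Output directory (created if missing).
#' @return data.frame manifest: `file`, `md5`.
#' @export
write_fixture <- function(truth, sim, outdir) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)
  p <- function(f) file.path(outdir, f)

  gtf <- p("models.gtf")
  .write_gtf(truth$loci, gtf)
  paths <- c(paths, gtf)

  fa <- p("transcripts.fa")
  .write_fasta(c(truth$mrna_seq, truth$lnc_seq), fa)
  paths <- c(paths, fa)
  mfa <- p("mirna_mature.fa")
  .write_fasta(chartr("U", "T", truth$mirna_seq), mfa)
  paths <- c(paths, mfa)
  pfa <- p("mirna_precursor.fa")
  .write_fasta(truth$precursor_seq, pfa)
  paths <- c(paths, pfa)

  for (cl in names(sim$counts)) {
    if (nrow(sim$counts[[cl]]) == 0) next
    f <- p(sprintf("counts_%s.tsv", tolower(cl)))
    write_count_tsv(sim$counts[[cl]], f)
    paths <- c(paths, f)
  }
  ss <- p("sample_sheet.tsv")
  utils::write.table(sim$design, ss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, ss)

  truth_tabs <- list(truth_planted_nr = truth$planted_nr,
                     truth_planted_nark = truth$planted_nark,
                     truth_triplets = truth$triplets,
                     truth_mres = truth$mre_truth,
                     truth_modules = truth$modules)
  for (nm in names(truth_tabs)) {
    if (is.null(truth_tabs[[nm]])) next
    f <- p(paste0(nm, ".tsv"))
    utils::write.table(truth_tabs[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}

.write_gtf <- function(loci, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
    loci$id, loci$id,
    ifelse(loci$class == "mRNA", "protein_coding", "lncRNA"))
  gene_attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', loci$id,
                        ifelse(loci$class == "mRNA", "protein_coding",
                               "lncRNA"))
  lines <- character(0)
  for (type in c("gene", "transcript", "exon")) {
    lines <- c(lines, sprintf("chr1\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              type, loci$start, loci$end, loci$strand,
                              if (type == "gene") gene_attrs else attrs))
  }
  ord <- order(rep(loci$start, 3), rep(1:3, each = nrow(loci)))
  writeLines(lines[ord], path)
}

.write_fasta <- function(seqs, path) {
  out <- character(2 * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
}

#' Write / read a count matrix TSV (first column `feature`)
#'
#' @param counts Matrix with rownames.
#' @param path File path.
#' @export
write_count_tsv <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) | m != round(m),
                 arr.ind = TRUE)
    stop("non-integer count in ", path,
         if (length(bad) > 0) sprintf(" (line %d, column %d)",
                                      bad[1, 1] + 1L, bad[1, 2] + 1L))
  }
  rownames(m) <- df[[1]]
  m
}

#' Simulate a module-structured expression matrix
#'
#' Gaussian log-expression with `n_modules` planted modules of `module_size`
#' genes each: gene = loading x module latent + sqrt(1 - loading^2) x noise.
#' Module 1's latent factor is the (standardized) genotype indicator of the
#' study design; the others are independent standard normals. Loadings are
#' uniform in `loading_range`, giving heterogeneous intramodular connectivity.
#'
#' @param n_modules Number of modules (default 4).
#' @param module_size Genes per module (default 50).
#' @param n_noise Additional unassigned background genes (default 100); real
#'   transcriptomes are mostly non-module genes, and the low-connectivity
#'   background is what gives the connectivity distribution its decaying,
#'   approximately scale-free shape.
#' @param loading_range Range of |loading| (default c(0.75, 0.98)).
#' @param seed RNG seed.
#' @return List: `expr` (samples x genes), `labels` (planted module per gene),
#'   `traits` (data.frame with numeric `genotype` 0/1), `design`.
#' @export
simulate_module_matrix <- function(n_modules = 4, module_size = 50,
                                   n_noise = 100,
                                   loading_range = c(0.75, 0.98), seed = 3) {
  set.seed(seed)
  design <- study_design()
  n <- nrow(design)
  geno <- as.numeric(design$genotype == "mutant")
  latents <- cbind(scale(geno)[, 1],
                   if (n_modules > 1) {
                     matrix(stats::rnorm(n * (n_modules - 1)), n)
                   })
  n_genes <- n_modules * module_size + n_noise
  labels <- c(rep(seq_len(n_modules), each = module_size),
              rep(0L, n_noise))
  expr <- matrix(0, n, n_genes)
  for (g in seq_len(n_genes)) {
    if (labels[g] == 0) {
      expr[, g] <- stats::rnorm(n)
    } else {
      a <- stats::runif(1, loading_range[1], loading_range[2])
      expr[, g] <- a * latents[, labels[g]] +
        sqrt(1 - a^2) * stats::rnorm(n)
    }
  }
  colnames(expr) <- sprintf("G%04d", seq_len(n_genes))
  rownames(expr) <- design$sample
  names(labels) <- colnames(expr)
  list(expr = expr, labels = labels,
       traits = data.frame(genotype = geno, row.names = design$sample),
       design = design)
}
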