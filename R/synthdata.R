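#' Configuration for the synthetic-study generator
#'
#' Defines a self-consistent tumor/normal study: negative-binomial count
#' matrices for miRNA, lncRNA and mRNA with planted differential expression,
#' curated-style interaction tables with planted true regulator-target
#' edges, sequences with planted miRNA seed sites, TF motifs planted in
#' promoter/enhancer windows, exponential survival with planted prognostic
#' effects, and immune-infiltration scores tied to a chosen lncRNA.
#'
#' Defaults emulate the design of a small tumor-dominated cohort (89 tumor
#' vs 3 adjacent-normal samples) with feature counts scaled to desk size.
#'
#' @param n_tumor,n_normal Sample counts per group.
#' @param n_mirna,n_lncrna,n_mrna Feature counts per class.
#' @param frac_de Fraction of features per class planted as differentially
#'   expressed (tumor vs normal), random sign.
#' @param log2fc_de Planted absolute log2 fold change for DE features.
#' @param nb_dispersion NB dispersion phi >= 0 (variance = mu + phi mu^2);
#'   0 means Poisson counts.
#' @param n_true_edges Number of planted true miRNA->target edges (split
#'   between mRNA and lncRNA targets).
#' @param edge_effect Latent-regulation strength in `[0, 1]`: each target's
#'   mean is multiplied by `exp(-edge_effect * z)` where `z` is its
#'   regulator's standardized latent per-sample level.
#' @param n_triplets Planted ceRNA (lncRNA, miRNA, mRNA) triplets; the
#'   lncRNA and mRNA share the same miRNA repressor.
#' @param n_prognostic Number of features with a planted survival effect.
#' @param beta_prognostic Log-hazard per unit of (centered) log2 expression.
#' @param censor_rate Target fraction of censored tumor samples.
#' @param motif_width Width of planted TF motifs (bases).
#' @param n_tf Number of TF motifs to plant.
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_tumor = 89L, n_normal = 3L,
                         n_mirna = 100L, n_lncrna = 60L, n_mrna = 300L,
                         frac_de = 0.25, log2fc_de = 3,
                         nb_dispersion = 0.1,
                         n_true_edges = 60L, edge_effect = 0.5,
                         n_triplets = 8L,
                         n_prognostic = 5L, beta_prognostic = 0.7,
                         censor_rate = 0.3,
                         motif_width = 8L, n_tf = 3L,
                         seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_mirna = as.integer(n_mirna), n_lncrna = as.integer(n_lncrna),
              n_mrna = as.integer(n_mrna),
              frac_de = frac_de, log2fc_de = log2fc_de,
              nb_dispersion = nb_dispersion,
              n_true_edges = as.integer(n_true_edges),
              edge_effect = edge_effect,
              n_triplets = as.integer(n_triplets),
              n_prognostic = as.integer(n_prognostic),
              beta_prognostic = beta_prognostic,
              censor_rate = censor_rate,
              motif_width = as.integer(motif_width), n_tf = as.integer(n_tf),
              seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_mirna", "n_lncrna", "n_mrna",
              "n_true_edges", "n_triplets", "n_prognostic", "motif_width",
              "n_tf")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("invalid config: '", nm, "' must be a non-negative count")
  for (nm in c("frac_de", "censor_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("invalid config: '", nm, "' must lie in [0, 1]")
  if (cfg$edge_effect < 0 || cfg$edge_effect > 1)
    stop("invalid config: 'edge_effect' must lie in [0, 1]")
  if (cfg$nb_dispersion < 0)
    stop("invalid config: 'nb_dispersion' must be >= 0")
  if (cfg$n_triplets > min(cfg$n_lncrna, cfg$n_mrna))
    stop("invalid config: n_triplets exceeds min(n_lncrna, n_mrna)")
  class(cfg) <- "synth_config"
  cfg
}

rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

rand_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

rc_dna <- function(s) {
  chartr("ACGTU", "TGCAA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a synthetic regulatory study with known ground truth
#'
#' Draws the full input bundle the pipeline consumes, together with a
#' `truth` record of everything planted, for recovery and calibration
#' testing. See [synth_config()] for the generative model. With the same
#' config (including its seed) the output is bit-identical across calls.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_study` with elements `expr` (list of raw
#'   `ExpressionMatrix`: `miRNA`, `lncRNA`, `mRNA`), `groups` (factor
#'   tumor/normal per sample), `clinical` (tumor samples), `interactions`
#'   (curated-style edge table: true edges plus decoys), `sequences` (list
#'   `mirna`, `lncrna`, `mrna` of named character vectors), `pwms` (list of
#'   probability matrices), `promoters` (named DNA sequences, one per
#'   lncRNA), `tss` (named TSS coordinate per lncRNA), `enhancers`
#'   (interval data frame), `tf_list`, `infiltration` (samples x cell types)
#'   and `truth`.
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_s <- config$n_tumor + config$n_normal
  samples <- sprintf("S%03d", seq_len(n_s))
  groups <- factor(rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)),
                   levels = c("normal", "tumor"))
  names(groups) <- samples

  ids <- list(miRNA = sprintf("miR-%03d", seq_len(config$n_mirna)),
              lncRNA = sprintf("LNC%03d", seq_len(config$n_lncrna)),
              mRNA = sprintf("GENE%04d", seq_len(config$n_mrna)))

  # planted DE features: random subset per class, up/down signs balanced
  # (keeps the class library sizes roughly comparable between groups, so
  # total-count normalisation is not dominated by the planted mass)
  de <- lapply(ids, function(v) {
    k <- floor(config$frac_de * length(v))
    f <- sample(v, k)
    sgn <- rep(c(1, -1), length.out = k)
    stats::setNames(sample(sgn), f)
  })

  de_mir <- names(de$miRNA)
  de_mrna <- names(de$mRNA)
  de_lnc <- names(de$lncRNA)

  # planted ceRNA triplets first: one shared miRNA repressing a
  # (lncRNA, mRNA) pair; the pair's correlation comes entirely from that
  # shared repressor, so triplet members take no further regulators below
  triplets <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                         mrna_id = character(0), stringsAsFactors = FALSE)
  n_tri <- min(config$n_triplets, length(de_mir),
               length(de_lnc), length(de_mrna))
  if (n_tri > 0) {
    tri_l <- sample(de_lnc, n_tri)
    tri_m <- sample(de_mrna, n_tri)
    tri_r <- sample(de_mir, n_tri, replace = length(de_mir) < n_tri)
    triplets <- data.frame(lncrna_id = tri_l, mirna_id = tri_r,
                           mrna_id = tri_m, stringsAsFactors = FALSE)
  }
  true_edges <- rbind(
    data.frame(regulator_id = triplets$mirna_id,
               target_id = triplets$lncrna_id,
               target_class = rep("lncRNA", nrow(triplets)),
               stringsAsFactors = FALSE),
    data.frame(regulator_id = triplets$mirna_id,
               target_id = triplets$mrna_id,
               target_class = rep("mRNA", nrow(triplets)),
               stringsAsFactors = FALSE))

  # remaining true edges: DE miRNA regulators against DE targets that are
  # not triplet members
  pool_m <- setdiff(de_mrna, triplets$mrna_id)
  pool_l <- setdiff(de_lnc, triplets$lncrna_id)
  n_left <- max(0L, config$n_true_edges - nrow(true_edges))
  n_edge_mrna <- min(length(pool_m), ceiling(n_left * 2 / 3))
  n_edge_lnc <- min(length(pool_l), n_left - n_edge_mrna)
  if (length(de_mir) > 0 && n_edge_mrna + n_edge_lnc > 0) {
    true_edges <- rbind(true_edges, data.frame(
      regulator_id = sample(de_mir, n_edge_mrna + n_edge_lnc, replace = TRUE),
      target_id = c(sample(pool_m, n_edge_mrna), sample(pool_l, n_edge_lnc)),
      target_class = rep(c("mRNA", "lncRNA"), c(n_edge_mrna, n_edge_lnc)),
      stringsAsFactors = FALSE))
  }
  true_edges <- true_edges[!duplicated(true_edges[1:2]), , drop = FALSE]
  rownames(true_edges) <- NULL

  # a repressor and its target move in opposite directions between groups:
  # force each planted target's DE sign opposite to its (first) regulator's
  for (i in seq_len(nrow(true_edges))) {
    tcl <- true_edges$target_class[i]
    tid <- true_edges$target_id[i]
    reg_sign <- de$miRNA[[true_edges$regulator_id[i]]]
    de[[tcl]][[tid]] <- -reg_sign
  }

  # log-scale mean model per feature x sample; ceRNA-competent transcripts
  # (triplet members) get abundant baselines, as the competition mechanism
  # presumes well-expressed transcripts
  mu_log <- lapply(names(ids), function(cl) {
    base <- stats::rnorm(length(ids[[cl]]), mean = log(80), sd = 1)
    m <- matrix(base, nrow = length(ids[[cl]]), ncol = n_s,
                dimnames = list(ids[[cl]], samples))
    sgn <- de[[cl]]
    if (length(sgn))
      m[names(sgn), groups == "tumor"] <-
        m[names(sgn), groups == "tumor"] + sgn * config$log2fc_de * log(2)
    m
  })
  names(mu_log) <- names(ids)
  if (nrow(triplets) > 0) {
    for (i in seq_len(nrow(triplets))) {
      mu_log$lncRNA[triplets$lncrna_id[i], ] <-
        mu_log$lncRNA[triplets$lncrna_id[i], ] -
        mean(mu_log$lncRNA[triplets$lncrna_id[i], ]) + log(400)
      mu_log$mRNA[triplets$mrna_id[i], ] <-
        mu_log$mRNA[triplets$mrna_id[i], ] -
        mean(mu_log$mRNA[triplets$mrna_id[i], ]) + log(400)
    }
  }

  # latent per-sample regulator levels drive both the regulator's own counts
  # and (negatively) its targets' means
  regulators <- unique(true_edges$regulator_id)
  z <- matrix(stats::rnorm(length(regulators) * n_s), length(regulators), n_s,
              dimnames = list(regulators, samples))
  if (length(regulators))
    mu_log$miRNA[regulators, ] <- mu_log$miRNA[regulators, , drop = FALSE] +
      0.6 * z
  for (i in seq_len(nrow(true_edges))) {
    tcl <- true_edges$target_class[i]
    tid <- true_edges$target_id[i]
    mu_log[[tcl]][tid, ] <- mu_log[[tcl]][tid, ] -
      config$edge_effect * z[true_edges$regulator_id[i], ]
  }

  expr <- lapply(names(ids), function(cl) {
    mu <- exp(mu_log[[cl]])
    cnt <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                  nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
    expression_matrix(cnt, feature_class = cl, scale = "raw")
  })
  names(expr) <- names(ids)

  # curated-style interaction table: true edges plus random decoys
  n_decoy <- max(2L * nrow(true_edges), 40L)
  n_dec_m <- if (config$n_mrna > 0) ceiling(n_decoy / 2) else 0L
  n_dec_l <- if (config$n_lncrna > 0) floor(n_decoy / 2) else 0L
  decoys <- if (config$n_mirna > 0 && n_dec_m + n_dec_l > 0)
    data.frame(
      regulator_id = sample(ids$miRNA, n_dec_m + n_dec_l, replace = TRUE),
      target_id = c(sample(ids$mRNA, n_dec_m, replace = TRUE),
                    sample(ids$lncRNA, n_dec_l, replace = TRUE)),
      target_class = rep(c("mRNA", "lncRNA"), c(n_dec_m, n_dec_l)),
      stringsAsFactors = FALSE)
  else true_edges[0, , drop = FALSE]
  interactions <- rbind(cbind(true_edges, source = rep("planted", nrow(true_edges))),
                        cbind(decoys, source = rep("decoy", nrow(decoys))))
  interactions <- interactions[!duplicated(interactions[1:2]), , drop = FALSE]
  # a decoy duplicating a true pair keeps the 'planted' tag (true rows first)
  rownames(interactions) <- NULL

  # sequences: miRNAs over ACGU; transcripts over ACGT with exact seed sites
  # (reverse complement of miRNA positions 1-8) planted for true edges
  seqs <- list(
    mirna = stats::setNames(rand_seq(config$n_mirna, 22L, c("A", "C", "G", "U")),
                            ids$miRNA),
    lncrna = stats::setNames(rand_seq(config$n_lncrna, 300L, c("A", "C", "G", "T")),
                             ids$lncRNA),
    mrna = stats::setNames(rand_seq(config$n_mrna, 300L, c("A", "C", "G", "T")),
                           ids$mRNA))
  seed_sites <- data.frame(mirna_id = character(0), target_id = character(0),
                           offset = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(true_edges))) {
    mir <- true_edges$regulator_id[i]
    tid <- true_edges$target_id[i]
    pool <- if (true_edges$target_class[i] == "mRNA") "mrna" else "lncrna"
    # canonical 8mer: reverse complement of miRNA positions 2-8 plus an A
    # opposite position 1
    site <- paste0(rc_dna(substr(seqs$mirna[[mir]], 2L, 8L)), "A")
    tlen <- nchar(seqs[[pool]][[tid]])
    off <- sample.int(tlen - 8L, 1L)  # 1-based insert position, site len 8
    s <- seqs[[pool]][[tid]]
    substr(s, off, off + 7L) <- site
    seqs[[pool]][[tid]] <- s
    seed_sites <- rbind(seed_sites, data.frame(
      mirna_id = mir, target_id = tid, offset = off - 1L,
      stringsAsFactors = FALSE))
  }

  # TF motifs: sharp columns (consensus prob 0.91) => high information content
  tf_ids <- if (config$n_tf > 0) sprintf("TF%02d", seq_len(config$n_tf)) else character(0)
  pwms <- lapply(tf_ids, function(tf) {
    cons <- sample(c("A", "C", "G", "T"), config$motif_width, replace = TRUE)
    p <- matrix(0.03, 4L, config$motif_width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(config$motif_width)) p[cons[j], j] <- 0.91
    p
  })
  names(pwms) <- tf_ids

  # lncRNA promoters: 4 kb window round a synthetic TSS, consensus planted
  tss <- stats::setNames(sample(5000:50000, config$n_lncrna, replace = TRUE),
                         ids$lncRNA)
  flank <- 2000L
  promoters <- stats::setNames(
    rand_seq(config$n_lncrna, 2L * flank, c("A", "C", "G", "T")), ids$lncRNA)
  motif_sites <- data.frame(motif_id = character(0), sequence_id = character(0),
                            offset = integer(0), strand = character(0),
                            stringsAsFactors = FALSE)
  if (length(tf_ids) > 0 && config$n_lncrna > 0) {
    for (tf in tf_ids) {
      n_hit <- min(4L, config$n_lncrna)
      targets <- sample(ids$lncRNA, n_hit)
      cons <- paste(rownames(pwms[[tf]])[apply(pwms[[tf]], 2L, which.max)],
                    collapse = "")
      for (tid in targets) {
        off <- sample.int(2L * flank - config$motif_width, 1L)
        s <- promoters[[tid]]
        substr(s, off, off + config$motif_width - 1L) <- cons
        promoters[[tid]] <- s
        motif_sites <- rbind(motif_sites, data.frame(
          motif_id = tf, sequence_id = tid, offset = off - 1L, strand = "+",
          stringsAsFactors = FALSE))
      }
    }
  }

  # enhancers: half within the +/-2 kb window of some lncRNA TSS, half far away
  enhancers <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          stringsAsFactors = FALSE)
  if (config$n_lncrna > 0) {
    n_enh <- max(10L, config$n_lncrna %/% 3L)
    enh_near <- sample(ids$lncRNA, ceiling(n_enh / 2), replace = TRUE)
    near_start <- tss[enh_near] + sample(-flank:(flank - 400L), length(enh_near),
                                         replace = TRUE)
    far_start <- sample(100000:200000, floor(n_enh / 2), replace = TRUE)
    enhancers <- data.frame(
      chrom = "chrS",
      start = pmax(0L, as.integer(c(near_start, far_start))),
      end = as.integer(c(near_start, far_start)) + 400L,
      name = sprintf("ENH%03d", seq_len(length(near_start) + length(far_start))),
      stringsAsFactors = FALSE)
  }

  # TF list: motif TFs aliased onto mRNA ids so they participate in the
  # miRNA-mRNA network, plus the motif ids themselves
  tf_genes <- if (length(de_mrna) >= config$n_tf && config$n_tf > 0)
    sample(de_mrna, config$n_tf) else character(0)
  tf_list <- unique(c(tf_genes, tf_ids))

  # survival: exponential hazard driven by planted prognostic features
  tumor <- samples[groups == "tumor"]
  progn_pool <- c(ids$miRNA, ids$lncRNA, ids$mRNA)
  progn <- if (config$n_prognostic > 0)
    sample(progn_pool, config$n_prognostic) else character(0)
  log2_all <- rbind(log2(unclass(expr$miRNA) + 1),
                    log2(unclass(expr$lncRNA) + 1),
                    log2(unclass(expr$mRNA) + 1))
  lp <- rep(0, length(tumor))
  if (length(progn)) {
    x <- log2_all[progn, tumor, drop = FALSE]
    xc <- sweep(x, 1L, rowMeans(x))  # centering leaves Cox coefficients unchanged
    lp <- as.vector(config$beta_prognostic * colSums(xc))
  }
  h0 <- 0.002
  rate <- h0 * exp(lp)
  t_event <- stats::rexp(length(tumor), rate)
  clinical <- if (config$censor_rate > 0 && config$censor_rate < 1) {
    # independent exponential censoring; P(censored | lambda) = g/(g+lambda),
    # so solve mean_s g/(g+lambda_s) = censor_rate for the censoring rate g
    target <- config$censor_rate
    g <- stats::uniroot(function(g) mean(g / (g + rate)) - target,
                        lower = 1e-12, upper = max(rate) * 1e6,
                        extendInt = "upX", tol = 1e-12)$root
    t_cens <- stats::rexp(length(tumor), g)
    data.frame(sample_id = tumor, time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens), stringsAsFactors = FALSE)
  } else if (config$censor_rate == 0) {
    data.frame(sample_id = tumor, time = t_event, event = 1L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = tumor, time = t_event, event = 0L,
               stringsAsFactors = FALSE)
  }

  # infiltration scores: one lncRNA planted at correlation ~0.5 with one cell type
  cells <- c("B.cell", "T.cell.CD4", "T.cell.CD8", "Neutrophil",
             "Macrophage", "Dendritic")
  infil <- matrix(stats::rnorm(length(tumor) * length(cells)),
                  nrow = length(tumor), dimnames = list(tumor, cells))
  infil_pair <- NULL
  if (config$n_lncrna > 0) {
    lnc_pl <- sample(ids$lncRNA, 1L)
    cell_pl <- sample(cells, 1L)
    xl <- log2(unclass(expr$lncRNA)[lnc_pl, tumor] + 1)
    r_target <- 0.5
    infil[, cell_pl] <- r_target * as.vector(base::scale(xl)) +
      sqrt(1 - r_target^2) * stats::rnorm(length(tumor))
    infil_pair <- c(lncrna = lnc_pl, cell_type = cell_pl)
  }

  truth <- list(de_features = de, true_edges = true_edges,
                triplets = triplets,
                prognostic = stats::setNames(
                  rep(config$beta_prognostic, length(progn)), progn),
                motif_sites = motif_sites, seed_sites = seed_sites,
                infiltration_pair = infil_pair)

  structure(list(expr = expr, groups = groups, clinical = clinical,
                 interactions = interactions, sequences = seqs,
                 pwms = pwms, promoters = promoters, tss = tss,
                 enhancers = enhancers, tf_list = tf_list,
                 infiltration = infil, truth = truth, config = config),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic regulatory study\n")
  cat(sprintf("  samples: %d tumor + %d normal\n", cfg$n_tumor, cfg$n_normal))
  cat(sprintf("  features: %d miRNA, %d lncRNA, %d mRNA (frac DE %.2f)\n",
              cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna, cfg$frac_de))
  cat(sprintf("  planted: %d true edges, %d triplets, %d prognostic features\n",
              nrow(x$truth$true_edges), nrow(x$truth$triplets),
              length(x$truth$prognostic)))
  invisible(x)
}
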