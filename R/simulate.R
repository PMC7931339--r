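# Seeded generators for every input the pipeline consumes, with
# ground-truth manifests.  Each generator is a pure function of
# (parameters, seed): the RNG state is set locally (Mersenne-Twister,
# Inversion) and restored on exit, so regeneration is byte-identical.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Simulate a pooled two-plate qPCR microRNA array
#'
#' Emulates a one-pool-per-group low-density array screen: per assay a
#' base Cq is drawn uniformly, the control well adds noise, the
#' intervention well subtracts the planted delta-Cq effect (positive
#' effect = up in intervention, i.e. fewer cycles) and adds an
#' intensity-dependent bias polynomial evaluated at the base Cq plus
#' noise. High-Cq wells drop out (become undetermined) with logistic
#' probability. Assays alternate across plates A and B.
#'
#' @param n_assays Number of assays (default 667, >= 20).
#' @param base_cq_range Uniform range of base Cq values (default
#'   `c(14, 36)`, bracketing a typical observed 11.8-37.4 span).
#' @param de_spec Named numeric vector of planted delta-Cq effects
#'   (names = assay ids such as `"assay_0001"`), or `NULL` for none.
#' @param bias_coeffs Polynomial coefficients (intercept first) of the
#'   intensity-dependent bias in the intervention channel, evaluated at
#'   `(base - 25)/11` for conditioning; default `c(0, 0, 0)`.
#' @param noise_sd Well noise SD in cycles (default 0.25, a typical
#'   qPCR technical-replicate scale).
#' @param dropout_midpoint,dropout_scale Logistic dropout: a well with
#'   Cq value v is undetermined with probability
#'   `plogis((v - midpoint)/scale)` (defaults 38 and 0.5).
#' @param seed Integer seed.
#' @return A list with `cq` (a `cq_matrix`) and `truth` (a
#'   `simulation_truth` list: `seed`, `params`, `planted_de`,
#'   `bias_coeffs`, `base_cq`).
#' @export
simulate_cq_array <- function(n_assays = 667, base_cq_range = c(14, 36),
                              de_spec = NULL, bias_coeffs = c(0, 0, 0),
                              noise_sd = 0.25, dropout_midpoint = 38,
                              dropout_scale = 0.5, seed = 1) {
  if (n_assays < 20) stop_fmt("n_assays must be >= 20, got %d", n_assays)
  if (length(base_cq_range) != 2 || diff(base_cq_range) <= 0) {
    stop_fmt("base_cq_range must be an increasing length-2 range")
  }
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  assay_ids <- sprintf("assay_%04d", seq_len(n_assays))
  if (!is.null(de_spec)) {
    if (is.null(names(de_spec)) ||
        !all(names(de_spec) %in% assay_ids)) {
      stop_fmt("de_spec must be named by assay ids assay_0001..assay_%04d",
               n_assays)
    }
  }
  with_local_seed(seed, {
    base <- stats::runif(n_assays, base_cq_range[1], base_cq_range[2])
    de <- stats::setNames(rep(0, n_assays), assay_ids)
    if (!is.null(de_spec)) de[names(de_spec)] <- de_spec
    z <- (base - 25) / 11
    bias <- drop(outer(z, seq_along(bias_coeffs) - 1, `^`) %*% bias_coeffs)
    cq_con <- base + stats::rnorm(n_assays, 0, noise_sd)
    cq_n3 <- base - de + bias + stats::rnorm(n_assays, 0, noise_sd)
    plate <- rep(c("A", "B"), length.out = n_assays)
    long <- data.frame(
      assay_id = rep(assay_ids, 2),
      plate = rep(plate, 2),
      group = rep(c("Con", "N3"), each = n_assays),
      cq = c(cq_con, cq_n3), stringsAsFactors = FALSE)
    p_drop <- stats::plogis((long$cq - dropout_midpoint) / dropout_scale)
    long$undetermined <- stats::runif(nrow(long)) < p_drop
    long$cq[long$undetermined] <- NA_real_
    truth <- structure(list(
      seed = seed,
      params = list(n_assays = n_assays, base_cq_range = base_cq_range,
                    bias_coeffs = bias_coeffs, noise_sd = noise_sd,
                    dropout_midpoint = dropout_midpoint,
                    dropout_scale = dropout_scale),
      planted_de = de[de != 0], bias_coeffs = bias_coeffs,
      base_cq = stats::setNames(base, assay_ids)),
      class = "simulation_truth")
    list(cq = as_cq_matrix(long), truth = truth)
  })
}

# substitute k random seed positions so the planted window has Hamming
# distance exactly k from the perfect site
mutate_window <- function(window, k) {
  if (k == 0) return(window)
  pos <- sample(seq_along(window), k)
  for (p in pos) {
    window[p] <- sample(setdiff(RNA_LEVELS, window[p]), 1)
  }
  window
}

#' Simulate transcripts with planted microRNA seed sites
#'
#' Generates i.i.d.-uniform-background transcripts partitioned into
#' 5'UTR/CDS/3'UTR, then plants seed sites: the reverse complement of
#' the given miRNA's seed with the requested number of substitutions at
#' random seed positions. After planting, each site is re-scanned to
#' confirm its recorded mismatch count (a plant destroyed by overlap is
#' re-drawn; after 100 failed attempts an error is raised).
#'
#' @param n_genes Number of transcripts.
#' @param length_range Transcript length range (uniform; min >= 60).
#' @param region_fracs Length fractions of 5'UTR/CDS/3'UTR (default
#'   `c(0.15, 0.55, 0.30)`).
#' @param mirnas Named list of `mature_mirna` objects used for planting.
#' @param plant_spec Data frame with columns `gene` (index or id),
#'   `mirna_id`, `mismatches` and optionally `position` (site start;
#'   random if `NA`), or `NULL` for no plants.
#' @param seed Integer seed.
#' @return A list with `transcripts` (named list of
#'   `transcript_regions`) and `truth` (`simulation_truth` with
#'   `planted_sites`: gene, mirna_id, start, end, mismatches, region).
#' @export
simulate_transcripts <- function(n_genes = 20, length_range = c(300, 1000),
                                 region_fracs = c(0.15, 0.55, 0.30),
                                 mirnas = NULL, plant_spec = NULL,
                                 seed = 1) {
  if (length_range[1] < 60) stop_fmt("transcript lengths must be >= 60")
  stopifnot(length(region_fracs) == 3,
            abs(sum(region_fracs) - 1) < 1e-8)
  with_local_seed(seed, {
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    len_pool <- seq(length_range[1], length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n_genes, replace = TRUE)]
    seqs <- lapply(lens, function(L) sample(RNA_LEVELS, L, replace = TRUE))
    regions <- lapply(lens, function(L) {
      b1 <- max(1, round(L * region_fracs[1]))
      b2 <- max(b1 + 1, round(L * (region_fracs[1] + region_fracs[2])))
      data.frame(label = c("5UTR", "CDS", "3UTR"),
                 start = c(1, b1 + 1, b2 + 1),
                 end = c(b1, b2, L), stringsAsFactors = FALSE)
    })
    planted <- NULL
    if (!is.null(plant_spec) && nrow(plant_spec) > 0) {
      stopifnot(all(c("gene", "mirna_id", "mismatches") %in%
                      names(plant_spec)))
      if (is.null(plant_spec$position)) plant_spec$position <- NA_integer_
      planted <- plant_spec
      planted$start <- NA_integer_
      planted$end <- NA_integer_
      planted$region <- NA_character_
      occupied <- vector("list", n_genes)  # windows already planted per gene
      for (i in seq_len(nrow(plant_spec))) {
        g <- plant_spec$gene[i]
        gi <- if (is.numeric(g)) g else match(g, gene_ids)
        mir <- mirnas[[plant_spec$mirna_id[i]]]
        if (is.null(mir)) {
          stop_fmt("plant_spec miRNA %s not in mirnas",
                   plant_spec$mirna_id[i])
        }
        seed_chars <- strsplit(extract_seed(mir), "")[[1]]
        perfect <- rev(rna_complement(seed_chars))
        k <- plant_spec$mismatches[i]
        L <- lens[gi]
        ok <- FALSE
        for (attempt in 1:100) {
          pos <- plant_spec$position[i]
          if (is.na(pos)) pos <- sample.int(L - 6, 1)
          # overlapping an earlier plant would corrupt it: redraw
          if (any(vapply(occupied[[gi]], function(w) {
            abs(w - pos) < 7
          }, logical(1)))) {
            if (!is.na(plant_spec$position[i])) {
              stop_fmt("plant %d collides with an earlier plant", i)
            }
            next
          }
          window <- mutate_window(perfect, k)
          cand <- seqs[[gi]]
          cand[pos:(pos + 6)] <- window
          # verify the plant survived (exact mismatch count at pos)
          tr <- transcript_regions(gene_ids[gi],
                                   paste(cand, collapse = ""),
                                   regions[[gi]])
          hits <- find_seed_sites(mir, tr, max_mismatch = 2)
          hit <- hits[hits$start == pos, , drop = FALSE]
          if (nrow(hit) == 1 && hit$mismatches == k) {
            seqs[[gi]] <- cand
            planted$start[i] <- pos
            planted$end[i] <- pos + 6L
            planted$region[i] <- hit$region
            occupied[[gi]] <- c(occupied[[gi]], pos)
            ok <- TRUE
            break
          }
          if (!is.na(plant_spec$position[i])) break  # fixed position: no redraw
        }
        if (!ok) {
          stop_fmt("failed to plant site %d (gene %s) after 100 attempts",
                   i, gene_ids[gi])
        }
      }
    }
    transcripts <- lapply(seq_len(n_genes), function(i) {
      transcript_regions(gene_ids[i], paste(seqs[[i]], collapse = ""),
                         regions[[i]])
    })
    names(transcripts) <- gene_ids
    truth <- structure(list(
      seed = seed,
      params = list(n_genes = n_genes, length_range = length_range,
                    region_fracs = region_fracs),
      planted_sites = planted), class = "simulation_truth")
    list(transcripts = transcripts, truth = truth)
  })
}

#' Write simulated transcripts to FASTA plus a region TSV
#'
#' @param transcripts Named list of `transcript_regions`.
#' @param fasta_path,regions_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, regions_path) {
  seqs <- Biostrings::RNAStringSet(
    vapply(transcripts, function(t) t$sequence, character(1)))
  names(seqs) <- vapply(transcripts, function(t) t$gene_id, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  reg <- do.call(rbind, lapply(transcripts, function(t) {
    cbind(gene_id = t$gene_id, t$regions)
  }))
  utils::write.table(reg, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, regions = regions_path))
}

#' Simulate a mother-offspring cohort with validation qPCR records
#'
#' Generates a cohort with the four group-by-sex cells, log-normal amino
#' acid levels around supplied medians, per-target validation Cq values
#' with planted cell-mean shifts on the delta-Cq scale, outcomes built
#' from stated linear effects, and Bernoulli breastfeeding status.
#'
#' @param cell_counts Named counts for `Con-F`, `Con-M`, `N3-F`, `N3-M`
#'   (defaults 11, 9, 10, 11; each >= 3).
#' @param targets Character vector of expression targets (default
#'   `c("miR-99a", "mTOR", "SLC7A5", "SLC6A6")`).
#' @param cell_effects Named list per target of named delta-Cq shifts per
#'   cell (negative shift = higher expression); cells omitted shift 0.
#' @param cohort_betas Data frame with columns `outcome`, `predictor`,
#'   `beta` defining planted linear outcome effects, or `NULL`.
#' @param outcome_noise_sd Named vector of outcome noise SDs (default 1
#'   for any outcome not named).
#' @param amino_acid_medians Named medians (micromol/L) for the
#'   log-normal amino-acid columns; defaults use week-15 maternal plasma
#'   scales (Tau 106.5, Trp 41.3).
#' @param expr_noise_sd Delta-Cq noise SD (default 0.6, matching
#'   validation-scale biological scatter).
#' @param ref_targets Reference-gene ids for the validation records
#'   (default `c("RNU24", "RNU6b", "miR-26b")`).
#' @param breastfeeding_p Probability of "fully" breastfed (default 0.6).
#' @param seed Integer seed.
#' @return A list with `cohort` (one row per pair), `validation` (long
#'   Cq records for [delta_cq_table()]), and `truth`.
#' @export
simulate_cohort <- function(cell_counts = c(`Con-F` = 11, `Con-M` = 9,
                                            `N3-F` = 10, `N3-M` = 11),
                            targets = c("miR-99a", "mTOR", "SLC7A5",
                                        "SLC6A6"),
                            cell_effects = NULL, cohort_betas = NULL,
                            outcome_noise_sd = NULL,
                            amino_acid_medians = c(p15_tau = 106.5,
                                                   p15_trp = 41.3,
                                                   p32_tau = 99.0,
                                                   p32_trp = 38.0,
                                                   pl_tau = 330.0,
                                                   pl_trp = 2.6,
                                                   uc_tau = 550.0,
                                                   uc_trp = 151.0),
                            expr_noise_sd = 0.6,
                            ref_targets = c("RNU24", "RNU6b", "miR-26b"),
                            breastfeeding_p = 0.6, seed = 1) {
  stopifnot(all(cell_labels %in% names(cell_counts)))
  if (any(cell_counts < 3)) stop_fmt("every cell needs >= 3 pairs")
  n <- sum(cell_counts)
  with_local_seed(seed, {
    cells <- rep(names(cell_counts), cell_counts)
    cohort <- data.frame(
      pair_id = sprintf("pair_%02d", seq_len(n)),
      group = sub("-.*", "", cells), sex = sub(".*-", "", cells),
      stringsAsFactors = FALSE)
    # log-normal amino acids; sdlog 0.3 gives quartile spreads like
    # printed cohort tables
    for (aa in names(amino_acid_medians)) {
      cohort[[aa]] <- stats::rlnorm(n, log(amino_acid_medians[[aa]]), 0.3)
    }
    cohort$breastfeeding <- ifelse(stats::runif(n) < breastfeeding_p,
                                   "fully", "partial/formula")
    # expression delta-Cq per target: baseline + planted cell shift + noise
    for (tg in targets) {
      shift <- stats::setNames(rep(0, 4), cell_labels)
      eff <- cell_effects[[tg]]
      if (!is.null(eff)) shift[names(eff)] <- eff
      col <- paste0("dcq_", gsub("[^A-Za-z0-9]", "_", tg))
      cohort[[col]] <- 5 + shift[cells] + stats::rnorm(n, 0, expr_noise_sd)
    }
    # outcomes from planted betas
    if (!is.null(cohort_betas) && nrow(cohort_betas) > 0) {
      stopifnot(all(c("outcome", "predictor", "beta") %in%
                      names(cohort_betas)))
      for (oc in unique(cohort_betas$outcome)) {
        rows <- cohort_betas[cohort_betas$outcome == oc, , drop = FALSE]
        miss <- setdiff(rows$predictor, names(cohort))
        if (length(miss) > 0) {
          stop_fmt("cohort_betas predictor(s) not generated: %s",
                   paste(miss, collapse = ", "))
        }
        sd_oc <- 1
        if (!is.null(outcome_noise_sd) && oc %in% names(outcome_noise_sd)) {
          sd_oc <- outcome_noise_sd[[oc]]
        }
        y <- stats::rnorm(n, 0, sd_oc)
        for (j in seq_len(nrow(rows))) {
          y <- y + rows$beta[j] * cohort[[rows$predictor[j]]]
        }
        cohort[[oc]] <- y
      }
    }
    # validation records: per-sample reference offset so the shift-
    # invariance of delta-Cq is exercised by construction
    sample_offset <- stats::rnorm(n, 0, 0.3)
    val <- do.call(rbind, lapply(seq_len(n), function(i) {
      ref_cq <- 18 + sample_offset[i] + stats::rnorm(length(ref_targets),
                                                     0, 0.15)
      tg_cols <- paste0("dcq_", gsub("[^A-Za-z0-9]", "_", targets))
      tgt_cq <- mean(18 + sample_offset[i]) +
        unlist(cohort[i, tg_cols, drop = TRUE])
      data.frame(sample_id = cohort$pair_id[i], group = cohort$group[i],
                 sex = cohort$sex[i],
                 target_id = c(ref_targets, targets),
                 cq = c(ref_cq, tgt_cq), stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
    truth <- structure(list(
      seed = seed,
      params = list(cell_counts = cell_counts, targets = targets,
                    expr_noise_sd = expr_noise_sd,
                    breastfeeding_p = breastfeeding_p),
      cell_effects = cell_effects, cohort_betas = cohort_betas),
      class = "simulation_truth")
    list(cohort = cohort, validation = val, truth = truth)
  })
}
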