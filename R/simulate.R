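#' Cohort simulation configuration
#'
#' Parameters for [simulate_cohort()]. Defaults emulate the structure of the
#' clinical study the pipeline targets: a biopsy cohort of 55 patients with
#' half of tumors in the luminal-low (non-responding) state — the monotherapy
#' biopsy cohort split evenly into non-responders and responders — a
#' monotherapy/combination arm split, a planted one-reference-SD shift of the
#' ERalpha-induced and luminal-TF genes in luminal-high tumors (MAPK-target
#' genes in luminal-low tumors), and exponential progression-free survival
#' calibrated so the planted median PFS ratio is 22 vs 6 months (hazard ratio
#' 6/22 for luminal-high vs luminal-low).
#'
#' @param n_patients Number of patients (>= 4).
#' @param frac_nr Fraction of patients in the luminal-low (non-responding)
#'   latent group.
#' @param frac_combo Fraction assigned to the combination arm.
#' @param sig_effect Planted mean shift (in reference-SD z-units) on the
#'   group-specific signature genes.
#' @param hazard_ratio Event-hazard ratio, luminal-high vs luminal-low.
#' @param median_pfs_lumlow Median PFS (months) of the luminal-low group.
#' @param censor_rate Probability a patient's time is censored (replaced by a
#'   uniform draw below the event time).
#' @param n_background_genes Number of effect-free background genes added to
#'   the signature genes.
#' @param noise_sd Expression noise SD (log2 units); planted shifts are
#'   `sig_effect * noise_sd` so they equal `sig_effect` after reference
#'   z-scoring.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 55, frac_nr = 0.5,
                              frac_combo = 0.3, sig_effect = 1,
                              hazard_ratio = 6 / 22, median_pfs_lumlow = 6,
                              censor_rate = 0.2, n_background_genes = 500,
                              noise_sd = 1, seed = 1L) {
  cfg <- list(n_patients = n_patients, frac_nr = frac_nr,
              frac_combo = frac_combo, sig_effect = sig_effect,
              hazard_ratio = hazard_ratio,
              median_pfs_lumlow = median_pfs_lumlow,
              censor_rate = censor_rate,
              n_background_genes = n_background_genes,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_patients < 4) abort("`n_patients` must be >= 4")
  for (f in c("frac_nr", "frac_combo", "censor_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]"))
  if (cfg$hazard_ratio <= 0) abort("`hazard_ratio` must be > 0")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (cfg$n_background_genes < 0) abort("`n_background_genes` must be >= 0")
  structure(cfg, class = "cohort_sim_config")
}

#' Simulate a clinical cohort with expression and survival
#'
#' Generates every patient-level input the pipeline consumes: a clinical
#' table (arm, PFS, event flag, best overall response, prior-CDK4/6i flag), a
#' baseline and an on-treatment (C2D8) expression matrix containing all
#' built-in signature genes plus background genes, and an effect-free
#' reference-cohort matrix of 138 samples for z-normalization.
#'
#' Each patient belongs to a latent `lum_high` or `lum_low` group (the
#' ground truth column `latent_group` is included for validation).
#' Luminal-high tumors carry a `+sig_effect` z-shift on the ERalpha-induced
#' and luminal-TF genes and draw survival times at hazard
#' `hazard_ratio * h_low`; luminal-low tumors carry the shift on MAPK-target
#' genes and have median PFS `median_pfs_lumlow`. On-treatment, luminal-high
#' tumors additionally lose `sig_effect` on the ERalpha-induced genes
#' (on-target drug effect in responders). Best overall response is PD exactly
#' for patients progressing before 2 months, otherwise drawn from CR/PR/SD/NE.
#'
#' @param config A [cohort_sim_config()].
#' @return List with tibbles `clinical`, `expr_baseline`, `expr_c2d8`,
#'   `reference` (expression tables have a `gene` column plus one column per
#'   sample).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_patients = 8, seed = 7))
#' names(sim)
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  sigs <- breast_signatures()
  sig_genes <- unique(unlist(sigs))
  n_genes <- length(sig_genes) + config$n_background_genes
  genes <- c(sig_genes,
             if (config$n_background_genes > 0)
               sprintf("BG%04d", seq_len(config$n_background_genes)))

  withr::with_seed(config$seed, {
    n <- config$n_patients
    patient <- sprintf("P%03d", seq_len(n))
    latent <- ifelse(runif(n) < config$frac_nr, "lum_low", "lum_high")
    arm <- ifelse(runif(n) < config$frac_combo, "combo", "mono")
    prior_cdk46i <- rbinom(n, 1, ifelse(arm == "combo", 0.05, 0.4))

    h_low <- log(2) / config$median_pfs_lumlow
    haz <- ifelse(latent == "lum_high", h_low * config$hazard_ratio, h_low)
    t_event <- rexp(n, rate = haz)
    censored <- runif(n) < config$censor_rate
    pfs <- ifelse(censored, t_event * runif(n), t_event)
    event <- as.integer(!censored)

    is_nr_rule <- event == 1 & pfs < 2
    cbor <- ifelse(is_nr_rule, "PD",
                   sample(c("CR", "PR", "SD", "NE"), n, replace = TRUE,
                          prob = c(0.08, 0.35, 0.52, 0.05)))

    clinical <- tibble::tibble(
      patient = patient, arm = arm, pfs_months = pfs, event = event,
      cbor = cbor, prior_cdk46i = prior_cdk46i, latent_group = latent
    )

    mu <- rnorm(n_genes, mean = 7, sd = 1.5)
    shift <- config$sig_effect * config$noise_sd
    hi_genes <- genes %in% c(sigs$era_induced, sigs$luminal_tf)
    lo_genes <- genes %in% sigs$mapk_target
    effect <- outer(hi_genes, latent == "lum_high") * shift +
      outer(lo_genes, latent == "lum_low") * shift

    base_m <- mu + effect +
      matrix(rnorm(n_genes * n, sd = config$noise_sd), n_genes, n)
    treat_effect <- effect -
      outer(genes %in% sigs$era_induced, latent == "lum_high") * shift
    c2d8_m <- mu + treat_effect +
      matrix(rnorm(n_genes * n, sd = config$noise_sd), n_genes, n)
    ref_m <- mu + matrix(rnorm(n_genes * 138, sd = config$noise_sd), n_genes, 138)

    as_tbl <- function(m, ids) {
      colnames(m) <- ids
      dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
    }
    list(
      clinical = clinical,
      expr_baseline = as_tbl(base_m, patient),
      expr_c2d8 = as_tbl(c2d8_m, patient),
      reference = as_tbl(ref_m, sprintf("R%03d", seq_len(138)))
    )
  })
}

#' Simulate read pileups at planted allele fractions
#'
#' Draws mutant-supporting read counts binomially at the planted variant
#' allele fraction, one row per sample x variant.
#'
#' @param planted Data frame with columns `sample`, `gene`, `variant`,
#'   `depth` (>= 0) and `vaf` (planted allele fraction in \[0, 1\]).
#' @param seed Integer seed.
#' @return Pileup tibble: `sample`, `gene`, `variant`, `depth`, `mut_reads`.
#' @examples
#' simulate_pileups(tibble::tibble(sample = "s1", gene = "ESR1",
#'                                 variant = "ESR1:Y537S", depth = 100,
#'                                 vaf = 0.1), seed = 2)
#' @export
simulate_pileups <- function(planted, seed = 1L) {
  stopifnot(is.data.frame(planted),
            all(c("sample", "gene", "variant", "depth", "vaf") %in% names(planted)))
  if (any(planted$depth < 0)) abort("depths must be >= 0")
  if (any(planted$vaf < 0 | planted$vaf > 1)) abort("VAFs must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      sample = planted$sample, gene = planted$gene, variant = planted$variant,
      depth = as.integer(planted$depth),
      mut_reads = rbinom(nrow(planted), planted$depth, planted$vaf)
    )
  })
}

#' Simulate IHC intensity tables
#'
#' Per sample, draws the four intensity-bucket percentages (0/1+/2+/3+) from
#' a Dirichlet distribution (gamma normalization) with the given
#' concentration parameters; each row sums to 100. A zero concentration puts
#' no mass in that bucket, so a degenerate concentration vector concentrates
#' all mass at one intensity.
#'
#' @param n_samples Number of samples.
#' @param concentration Length-4 non-negative Dirichlet concentration for
#'   buckets 0/1+/2+/3+ (at least one entry positive).
#' @param group Group label recorded per row.
#' @param seed Integer seed.
#' @return Tibble: `sample`, `group`, `pct0`, `pct1`, `pct2`, `pct3`.
#' @export
simulate_ihc <- function(n_samples, concentration = c(2, 2, 2, 2),
                         group = "all", seed = 1L) {
  stopifnot(n_samples >= 1, length(concentration) == 4)
  if (any(concentration < 0) || sum(concentration) == 0)
    abort("`concentration` must be non-negative with a positive sum")
  withr::with_seed(as.integer(seed), {
    g <- matrix(rgamma(n_samples * 4, shape = rep(concentration, each = n_samples)),
                nrow = n_samples)
    pct <- 100 * g / rowSums(g)
    tibble::tibble(
      sample = sprintf("%s_S%03d", group, seq_len(n_samples)), group = group,
      pct0 = pct[, 1], pct1 = pct[, 2], pct2 = pct[, 3], pct3 = pct[, 4]
    )
  })
}

#' Chromatin simulation configuration
#'
#' Parameters for [simulate_peaks_and_motifs()]. Defaults emulate the
#' resistance time-course structure: about a third of peaks differential
#' with gains outnumbering losses several-fold, an ERalpha (ESR1) motif
#' planted preferentially in lost ("down") peaks with a co-occurrence profile
#' giving roughly 70% ESR1-without-FOXA1 among ESR1/FOXA1 down peaks, and
#' FOX/TEAD/MEF2/STAT motifs planted in gained ("up") peaks. A subset of
#' genes receives pairs of FOXA1+partner co-occurring up-peaks near their TSS
#' and a planted expression increase per condition step.
#'
#' @param n_peaks Number of peaks on the single synthetic chromosome.
#' @param n_genes Number of annotated genes.
#' @param chrom_length Chromosome length (bp).
#' @param frac_up,frac_down Fractions of peaks in the up / down class.
#' @param motif_probs Data frame with columns `motif`, `p_up`, `p_down`,
#'   `p_unchanged` (per-class Bernoulli occurrence probabilities); `NULL` for
#'   the built-in default panel (ESR1, FOXA1, FOXM1, TEAD1, MEF2B, STAT5B,
#'   CTCF background).
#' @param n_trend_genes Number of genes planted with co-occurring
#'   FOXA1+partner up-sites and an expression trend (split evenly across the
#'   MEF2B/TEAD1/STAT5B partners; forced to 0 when `frac_up = 0`).
#' @param trend_effect Planted expression shift (log2 units) per condition
#'   step for trend genes.
#' @param seed Integer seed.
#' @return A `chromatin_sim_config` list.
#' @export
chromatin_sim_config <- function(n_peaks = 10000, n_genes = 500,
                                 chrom_length = 5e7, frac_up = 0.28,
                                 frac_down = 0.06, motif_probs = NULL,
                                 n_trend_genes = 150, trend_effect = 1,
                                 seed = 1L) {
  if (is.null(motif_probs)) {
    motif_probs <- tibble::tribble(
      ~motif,   ~p_up, ~p_down, ~p_unchanged,
      "ESR1",    0.05,  0.45,    0.10,
      "FOXA1",   0.40,  0.15,    0.10,
      "FOXM1",   0.35,  0.08,    0.08,
      "TEAD1",   0.30,  0.05,    0.08,
      "MEF2B",   0.25,  0.05,    0.06,
      "STAT5B",  0.25,  0.05,    0.06,
      "CTCF",    0.20,  0.20,    0.20
    )
  }
  cfg <- list(n_peaks = n_peaks, n_genes = n_genes,
              chrom_length = chrom_length, frac_up = frac_up,
              frac_down = frac_down, motif_probs = motif_probs,
              n_trend_genes = n_trend_genes, trend_effect = trend_effect,
              seed = as.integer(seed))
  stopifnot(is.data.frame(motif_probs),
            all(c("motif", "p_up", "p_down", "p_unchanged") %in% names(motif_probs)))
  pm <- as.matrix(motif_probs[c("p_up", "p_down", "p_unchanged")])
  if (any(pm < 0 | pm > 1)) abort("motif probabilities must lie in [0, 1]")
  if (cfg$frac_up < 0 || cfg$frac_down < 0 || cfg$frac_up + cfg$frac_down > 1)
    abort("`frac_up` and `frac_down` must be non-negative with sum <= 1")
  if (cfg$n_peaks < 10) abort("`n_peaks` must be >= 10")
  structure(cfg, class = "chromatin_sim_config")
}

#' Simulate peaks, motif hits, gene annotation and a trend expression table
#'
#' Generates the chromatin-arm inputs on one synthetic chromosome (`chrS`,
#' BED-convention 0-based half-open intervals, non-overlapping): a peak table
#' with per-peak log2 fold change and FDR consistent with the planted class
#' (`up`: log2FC >= 1 at FDR < 0.05; `down`: mirrored; `unchanged`:
#' |log2FC| < 1), a wide Bernoulli motif-hit table with per-class occurrence
#' probabilities, a gene annotation with TSS positions, and a
#' parental/2-month/resistant expression table in which trend genes (planted
#' with two FOXA1+partner co-occurring up-sites within 3 kb of their TSS)
#' gain `trend_effect` per condition step.
#'
#' @param config A [chromatin_sim_config()].
#' @return List: `peaks` (`chrom`, `start`, `end`, `peak_id`, `log2fc`,
#'   `fdr`, `class_planted`), `motif_hits` (wide logical), `genes` (`gene`,
#'   `chrom`, `tss`, `strand`), `trend_expr` (`gene`, `parental`, `m2`,
#'   `resistant`), and `trend_genes` (named list of planted gene sets per
#'   partner motif).
#' @export
simulate_peaks_and_motifs <- function(config = chromatin_sim_config()) {
  stopifnot(inherits(config, "chromatin_sim_config"))
  withr::with_seed(config$seed, {
    np <- config$n_peaks
    slot <- config$chrom_length / np
    width <- pmin(floor(runif(np, 200, 800)), slot - 1)
    start <- floor((seq_len(np) - 1) * slot + runif(np, 0, slot - width - 1))
    peaks <- tibble::tibble(
      chrom = "chrS", start = start, end = start + width,
      peak_id = sprintf("peak_%05d", seq_len(np)),
      class_planted = sample(c("up", "down", "unchanged"), np, replace = TRUE,
                             prob = c(config$frac_up, config$frac_down,
                                      1 - config$frac_up - config$frac_down))
    )

    # gene annotation: TSS uniform, away from chromosome edges
    ng <- config$n_genes
    genes <- tibble::tibble(
      gene = sprintf("G%04d", seq_len(ng)), chrom = "chrS",
      tss = floor(runif(ng, 10000, config$chrom_length - 10000)),
      strand = sample(c("+", "-"), ng, replace = TRUE)
    )

    # plant trend genes: two co-occurring FOXA1+partner up-peaks within 3 kb
    partners <- c("MEF2B", "TEAD1", "STAT5B")
    n_trend <- if (config$frac_up == 0) 0 else min(config$n_trend_genes, ng)
    forced <- list()
    trend_genes <- stats::setNames(vector("list", length(partners)), partners)
    if (n_trend > 0) {
      trend_idx <- sample.int(ng, n_trend)
      partner_of <- rep(partners, length.out = n_trend)
      # overwrite the two peaks whose slots flank each trend gene's TSS
      for (k in seq_len(n_trend)) {
        gi <- trend_idx[k]
        tss <- genes$tss[gi]
        slot_i <- min(max(1, floor(tss / slot) + 1), np - 1)
        for (pi in c(slot_i, slot_i + 1)) {
          w <- 300
          s <- min(max(0, tss + sample(c(-1500, 1200), 1) + sample.int(200, 1)),
                   config$chrom_length - w - 1)
          peaks$start[pi] <- s
          peaks$end[pi] <- s + w
          peaks$class_planted[pi] <- "up"
          forced[[length(forced) + 1]] <-
            list(peak = pi, partner = partner_of[k])
        }
      }
      for (p in partners)
        trend_genes[[p]] <- genes$gene[trend_idx[partner_of == p]]
    }

    cls <- peaks$class_planted
    lfc <- numeric(np); fdr <- numeric(np)
    up <- cls == "up"; dn <- cls == "down"; un <- cls == "unchanged"
    lfc[up] <- 1 + rgamma(sum(up), shape = 2, scale = 0.5)
    lfc[dn] <- -(1 + rgamma(sum(dn), shape = 2, scale = 0.5))
    lfc[un] <- runif(sum(un), -0.99, 0.99)
    fdr[up | dn] <- runif(sum(up | dn), 0, 0.049)
    fdr[un] <- runif(sum(un), 0, 0.999)
    peaks$log2fc <- lfc
    peaks$fdr <- fdr
    peaks <- peaks[c("chrom", "start", "end", "peak_id", "log2fc", "fdr",
                     "class_planted")]

    pm <- config$motif_probs
    hits <- tibble::tibble(peak_id = peaks$peak_id)
    for (i in seq_len(nrow(pm))) {
      pv <- c(up = pm$p_up[i], down = pm$p_down[i], unchanged = pm$p_unchanged[i])
      hits[[pm$motif[i]]] <- rbinom(np, 1, pv[cls]) == 1
    }
    # force planted co-occurrence on the trend-gene peaks
    for (f in forced) {
      hits$FOXA1[f$peak] <- TRUE
      hits[[f$partner]][f$peak] <- TRUE
    }

    is_trend <- genes$gene %in% unlist(trend_genes)
    basex <- rnorm(ng, 8, 1)
    mk <- function(step) basex + config$trend_effect * step * is_trend +
      rnorm(ng, 0, 0.1)
    trend_expr <- tibble::tibble(gene = genes$gene, parental = mk(0),
                                 m2 = mk(1), resistant = mk(2))

    list(peaks = peaks, motif_hits = hits, genes = genes,
         trend_expr = trend_expr, trend_genes = trend_genes)
  })
}
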