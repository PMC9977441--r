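#' Default planted loci for the toy genome
#'
#' A small panel of planted copy number loci covering the structures the
#' downstream models look for: a recurrent gained locus driving outcome
#' hazard (an MYC-like 8q surrogate), deletion loci whose frequency falls
#' with percent African ancestry (PTEN-like), and germline copy number
#' variant loci whose frequency rises steeply with ancestry (CCL3L1-like)
#' and which are present identically in normal tissue.
#'
#' Columns: `locus_id`, `chrom`, `start`, `end` (0-based half-open),
#' `somatic_effect` (log2 units when altered), `prob_base` (alteration
#' probability at ancestry fraction 0), `ancestry_slope` (logit units per
#' unit ancestry fraction) and `germline` (logical).
#'
#' @return Data frame of planted locus definitions.
#' @export
default_planted_loci <- function() {
  data.frame(
    locus_id = c("gain_hazard_8q", "del_ancestry_10q", "del_ancestry_11p",
                 "del_ancestry_17p", "germline_17q12_a", "germline_17q12_b"),
    chrom = c("chr3", "chr1", "chr2", "chr4", "chr5", "chr5"),
    start = c(20e6, 10e6, 30e6, 5e6, 12e6, 14e6),
    end = c(22e6, 11.5e6, 31.2e6, 6.1e6, 13e6, 15e6),
    somatic_effect = c(0.5, -0.5, -0.5, -0.5, 0.6, 0.6),
    prob_base = c(0.19, 0.45, 0.40, 0.40, 0.10, 0.10),
    ancestry_slope = c(0, -2, -2, -2, 3, 3),
    germline = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode
#' a grade-matched two-group prostate cohort of 145 + 145 tumors with a
#' normal-tissue reference cohort of 88 + 40, segment log2 ratios drawn
#' from a three-component loss/neutral/gain mixture, ancestry-dependent
#' planted alterations, exponential outcome hazards scaled by the gain
#' status of a designated hazard locus, administrative uniform censoring,
#' and a Treg fraction tied to true PGA through a Gaussian copula.
#'
#' @param n_tumor_groupA,n_tumor_groupB Tumor sample counts per group.
#' @param n_normal_groupA,n_normal_groupB Normal-tissue sample counts.
#' @param loci Planted locus table (see [default_planted_loci()]).
#' @param mixture_truth List with `means` (loss < neutral < gain, log2),
#'   `sds` (> 0) and `weights` (sum to 1) of the background segment
#'   mixture.
#' @param hazard_locus `locus_id` of the planted locus driving outcome
#'   hazard.
#' @param hazard_loghr Log hazard ratio per gain at the hazard locus.
#' @param treg_pga_rho Target Spearman correlation between the true Treg
#'   fraction and true PGA.
#' @param noise_sd Log2 noise SD on planted-locus segment means and on
#'   locus-level measurement.
#' @param n_null_loci Unplanted annotation loci added per cohort.
#' @param mean_breaks_per_chrom Poisson mean of background breakpoints per
#'   chromosome.
#' @param bin_size Base pairs per pseudo-bin (sets segment `n_bins`).
#' @param ancestry_shapes List of Beta shape pairs per group; defaults put
#'   one mode near 0.8 (group A) and one near 0 (group B).
#' @param bcr_base_rate,met_base_rate Baseline exponential event rates per
#'   unit time for the two outcomes.
#' @param censor_max Upper bound of the uniform administrative censoring
#'   time.
#' @param covariate_loghr Named log hazard ratios for `grade_high`,
#'   `age` (per year, centered) and `psa` (per ng/mL, centered).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tumor_groupA = 145, n_tumor_groupB = 145,
                       n_normal_groupA = 88, n_normal_groupB = 40,
                       loci = default_planted_loci(),
                       mixture_truth = list(
                         means = c(loss = -0.5, neutral = 0, gain = 0.5),
                         sds = c(loss = 0.08, neutral = 0.08, gain = 0.08),
                         weights = c(loss = 0.025, neutral = 0.95,
                                     gain = 0.025)),
                       hazard_locus = "gain_hazard_8q",
                       hazard_loghr = 0.8,
                       treg_pga_rho = 0.4,
                       noise_sd = 0.1,
                       n_null_loci = 400,
                       mean_breaks_per_chrom = 7,
                       bin_size = 1e5,
                       ancestry_shapes = list(groupA = c(8, 2),
                                              groupB = c(1.2, 20)),
                       bcr_base_rate = 0.06,
                       met_base_rate = 0.025,
                       censor_max = 15,
                       covariate_loghr = c(grade_high = 0.7, age = 0.02,
                                           psa = 0.01),
                       seed = 1L) {
  cfg <- list(n_tumor_groupA = n_tumor_groupA,
              n_tumor_groupB = n_tumor_groupB,
              n_normal_groupA = n_normal_groupA,
              n_normal_groupB = n_normal_groupB,
              loci = loci, mixture_truth = mixture_truth,
              hazard_locus = hazard_locus, hazard_loghr = hazard_loghr,
              treg_pga_rho = treg_pga_rho, noise_sd = noise_sd,
              n_null_loci = n_null_loci,
              mean_breaks_per_chrom = mean_breaks_per_chrom,
              bin_size = bin_size, ancestry_shapes = ancestry_shapes,
              bcr_base_rate = bcr_base_rate, met_base_rate = met_base_rate,
              censor_max = censor_max, covariate_loghr = covariate_loghr,
              seed = as.integer(seed))
  lab <- c("loss", "neutral", "gain")
  for (f in c("means", "sds", "weights")) {
    if (length(cfg$mixture_truth[[f]]) != 3)
      stop("mixture_truth$", f, " must have length 3")
    names(cfg$mixture_truth[[f]]) <- lab
  }
  with(cfg, {
    stopifnot(n_tumor_groupA >= 0, n_tumor_groupB >= 0,
              n_normal_groupA >= 0, n_normal_groupB >= 0)
    stopifnot(abs(sum(mixture_truth$weights) - 1) < 1e-8,
              all(mixture_truth$weights >= 0),
              all(mixture_truth$sds > 0))
    m <- mixture_truth$means
    if (!(m[1] < m[2] && m[2] < m[3]))
      stop("mixture_truth means must satisfy loss < neutral < gain")
    stopifnot(noise_sd >= 0, bin_size > 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

# Planted loci must not overlap on a chromosome: overlapping truth would
# be ambiguous.
check_planted_loci <- function(loci, genome) {
  stopifnot(all(c("locus_id", "chrom", "start", "end", "somatic_effect",
                  "prob_base", "ancestry_slope", "germline") %in% names(loci)))
  if (any(loci$end <= loci$start)) stop("planted loci with end <= start")
  bad <- setdiff(unique(loci$chrom), genome$chrom_names)
  if (length(bad)) stop("planted loci on unknown chromosomes: ",
                        paste(bad, collapse = ", "))
  lens <- stats::setNames(genome$chrom_lengths, genome$chrom_names)
  if (any(loci$start < 0) || any(loci$end > lens[loci$chrom]))
    stop("planted loci outside chromosome bounds")
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  same <- loci$chrom[-1] == loci$chrom[-nrow(loci)]
  if (nrow(loci) > 1 && any(same & loci$start[-1] < loci$end[-nrow(loci)]))
    stop("planted loci overlap on the same chromosome (ambiguous truth)")
  invisible(loci)
}

# Null annotation loci: random intervals avoiding the planted loci so the
# planted signal never leaks into nominally null loci.
draw_null_loci <- function(n, genome, planted, mean_len = 5e4) {
  if (n == 0)
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  lens <- stats::setNames(genome$chrom_lengths, genome$chrom_names)
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    chrom <- sample(genome$chrom_names, 1,
                    prob = genome$chrom_lengths / genome$total_size)
    len <- min(round(stats::rlnorm(1, log(mean_len), 0.5)) + 1000,
               lens[chrom] / 10)
    start <- floor(stats::runif(1, 0, lens[chrom] - len))
    end <- start + len
    pl <- planted[planted$chrom == chrom, , drop = FALSE]
    if (nrow(pl) && any(start < pl$end & end > pl$start)) next
    got <- got + 1L
    out[[got]] <- data.frame(locus_id = sprintf("null_%04d", got),
                             chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Segments for one sample: planted loci are carved out as dedicated
# segments (altered -> somatic_effect, else neutral); the remaining
# territory is cut at Poisson-uniform breakpoints into background
# segments whose states come from the truth mixture.
sample_segments <- function(sid, altered, config, genome, background) {
  mt <- config$mixture_truth
  lens <- stats::setNames(genome$chrom_lengths, genome$chrom_names)
  rows <- list()
  states <- list()
  for (ch in genome$chrom_names) {
    L <- lens[[ch]]
    pl <- config$loci[config$loci$chrom == ch, , drop = FALSE]
    pl <- pl[order(pl$start), , drop = FALSE]
    cuts <- sort(unique(c(0, L, pl$start, pl$end)))
    # background breakpoints in the gaps between planted loci
    k <- stats::rpois(1, config$mean_breaks_per_chrom)
    if (k > 0) {
      bp <- floor(stats::runif(k, 1, L))
      inside <- rep(FALSE, k)
      if (nrow(pl))
        for (i in seq_len(nrow(pl)))
          inside <- inside | (bp > pl$start[i] & bp < pl$end[i])
      cuts <- sort(unique(c(cuts, bp[!inside])))
    }
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1]
    n_seg <- length(starts)
    seg_state <- character(n_seg)
    seg_mean <- numeric(n_seg)
    for (i in seq_len(n_seg)) {
      hit <- which(pl$start == starts[i] & pl$end == ends[i])
      if (length(hit) == 1) {
        lid <- pl$locus_id[hit]
        if (isTRUE(altered[lid])) {
          seg_state[i] <- if (pl$somatic_effect[hit] > 0) "gain" else "loss"
          seg_mean[i] <- pl$somatic_effect[hit] +
            stats::rnorm(1, 0, config$noise_sd)
        } else {
          seg_state[i] <- "neutral"
          seg_mean[i] <- stats::rnorm(1, 0, config$noise_sd)
        }
      } else if (background) {
        st <- sample(c("loss", "neutral", "gain"), 1,
                     prob = mt$weights)
        seg_state[i] <- st
        seg_mean[i] <- stats::rnorm(1, mt$means[[st]], mt$sds[[st]])
      } else {
        seg_state[i] <- "neutral"
        seg_mean[i] <- stats::rnorm(1, 0, config$noise_sd)
      }
    }
    rows[[ch]] <- data.frame(
      sample_id = sid, chrom = ch, start = starts, end = ends,
      n_bins = pmax(1L, as.integer(round((ends - starts) / config$bin_size))),
      seg_mean = seg_mean, stringsAsFactors = FALSE)
    states[[ch]] <- seg_state
  }
  list(segments = do.call(rbind, rows), states = unlist(states, use.names = FALSE))
}

plant_alterations <- function(ancestry, loci, somatic = TRUE) {
  n <- length(ancestry)
  out <- matrix(FALSE, n, nrow(loci),
                dimnames = list(names(ancestry), loci$locus_id))
  for (j in seq_len(nrow(loci))) {
    if (!somatic && !loci$germline[j]) next
    if (loci$somatic_effect[j] == 0) next  # zero-effect loci are unaltered
    p <- stats::plogis(stats::qlogis(loci$prob_base[j]) +
                         loci$ancestry_slope[j] * ancestry)
    p[is.na(p)] <- loci$prob_base[j]  # slope 0 with prob_base 0/1
    out[, j] <- stats::runif(n) < p
  }
  out
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Draws a tumor cohort and a matched normal-tissue cohort over a toy
#' genome. Per-sample segments partition every chromosome; planted locus
#' alterations are Bernoulli with logistic probability in percent African
#' ancestry; germline-flagged loci alter normal-tissue samples by the same
#' law while somatic loci never do; the remaining genome carries
#' background segments drawn from the configured loss/neutral/gain
#' mixture (normal tissue stays copy-neutral outside germline loci).
#' Outcome times are exponential with hazard scaled by the hazard locus's
#' gain status and by clinical covariates, with uniform administrative
#' censoring. True per-sample cell-type fractions tie Treg content to
#' true PGA through a Gaussian copula on ranks.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_model()] (default [toy_genome()]).
#' @return A list of class `sim_cohort`: `segments`, `locus_matrix`,
#'   `clinical`, `annotation`, `normal` (list with `segments`,
#'   `locus_matrix`, `clinical`), and `truth` (planted `alterations`,
#'   per-segment `segment_states`, true `pga`, cell `fractions`,
#'   `normal_alterations`).
#' @export
simulate_cohort <- function(config = sim_config(), genome = toy_genome()) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_model"))
  check_planted_loci(config$loci, genome)
  set.seed(config$seed)
  nA <- config$n_tumor_groupA; nB <- config$n_tumor_groupB
  n <- nA + nB
  ids <- sprintf("T%03d", seq_len(n))
  group <- c(rep("groupA", nA), rep("groupB", nB))
  shA <- config$ancestry_shapes$groupA; shB <- config$ancestry_shapes$groupB
  ancestry <- stats::setNames(
    c(stats::rbeta(nA, shA[1], shA[2]), stats::rbeta(nB, shB[1], shB[2])),
    ids)

  clinical <- data.frame(
    sample_id = ids, group = group, ancestry_fraction = unname(ancestry),
    age = round(stats::rnorm(n, 61, 7), 1),
    psa = round(stats::rlnorm(n, 2, 0.7), 2),
    grade_group = sample(1:5, n, replace = TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.1, 0.1)),
    stringsAsFactors = FALSE)

  alterations <- plant_alterations(ancestry, config$loci, somatic = TRUE)

  seg_list <- vector("list", n)
  state_list <- vector("list", n)
  for (i in seq_len(n)) {
    alt_row <- stats::setNames(as.logical(alterations[i, ]),
                               colnames(alterations))
    ss <- sample_segments(ids[i], alt_row, config, genome,
                          background = TRUE)
    seg_list[[i]] <- ss$segments
    state_list[[i]] <- ss$states
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  segment_states <- unlist(state_list, use.names = FALSE)

  # true PGA from the planted per-segment states
  seg_len <- segments$end - segments$start
  alt <- segment_states != "neutral"
  alt_bp <- unname(rowsum(seg_len * alt, segments$sample_id)[ids, 1])
  true_pga <- data.frame(sample_id = ids,
                         pga_true = 100 * alt_bp / genome$total_size,
                         stringsAsFactors = FALSE)

  annotation <- rbind(
    config$loci[, c("locus_id", "chrom", "start", "end")],
    draw_null_loci(config$n_null_loci, genome, config$loci))
  lm_tumor <- summarize_loci(segments, annotation, genome)
  # locus-level measurement noise on top of the segment projection
  if (config$noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(lm_tumor$values), 0, config$noise_sd),
                    nrow = nrow(lm_tumor$values))
    lm_tumor$values <- lm_tumor$values + noise
  }

  # outcomes driven by gain status at the hazard locus
  hz <- config$hazard_locus
  gain_status <- if (hz %in% colnames(alterations)) alterations[, hz]
                 else rep(FALSE, n)
  ch <- config$covariate_loghr
  lp <- config$hazard_loghr * gain_status +
    ch[["grade_high"]] * grade_high(clinical$grade_group) +
    ch[["age"]] * (clinical$age - mean(clinical$age)) +
    ch[["psa"]] * (clinical$psa - mean(clinical$psa))
  draw_outcome <- function(base_rate) {
    t_event <- stats::rexp(n, rate = base_rate * exp(lp))
    t_cens <- stats::runif(n, 0, config$censor_max)
    list(time = pmax(pmin(t_event, t_cens), 1e-6),
         event = as.integer(t_event <= t_cens))
  }
  bcr <- draw_outcome(config$bcr_base_rate)
  met <- draw_outcome(config$met_base_rate)
  clinical$bcr_time <- bcr$time; clinical$bcr_event <- bcr$event
  clinical$met_time <- met$time; clinical$met_event <- met$event

  # Treg fraction tied to true PGA via a Gaussian copula on ranks
  cell_types <- c("Treg", "Bcell", "CD8T", "CD4T", "NK", "Macrophage",
                  "Neutrophil", "Eosinophil", "Endothelial", "Fibroblast")
  u_pga <- rank(true_pga$pga_true, ties.method = "average") / (n + 1)
  rho <- config$treg_pga_rho
  z <- rho * stats::qnorm(u_pga) + sqrt(1 - rho^2) * stats::rnorm(n)
  treg <- stats::qbeta(stats::pnorm(z), 4, 36)
  others <- matrix(stats::rgamma(n * (length(cell_types) - 1), shape = 2),
                   nrow = n)
  others <- others / rowSums(others) * (1 - treg)
  fractions <- cbind(Treg = treg, others)
  colnames(fractions) <- cell_types
  rownames(fractions) <- ids

  # normal-tissue cohort: germline loci only, copy-neutral background
  nnA <- config$n_normal_groupA; nnB <- config$n_normal_groupB
  nn <- nnA + nnB
  normal <- NULL
  normal_alterations <- NULL
  if (nn > 0) {
    nids <- sprintf("N%03d", seq_len(nn))
    ngroup <- c(rep("groupA", nnA), rep("groupB", nnB))
    nanc <- stats::setNames(
      c(stats::rbeta(nnA, shA[1], shA[2]), stats::rbeta(nnB, shB[1], shB[2])),
      nids)
    normal_alterations <- plant_alterations(nanc, config$loci,
                                            somatic = FALSE)
    nseg_list <- vector("list", nn)
    for (i in seq_len(nn))
      nseg_list[[i]] <- sample_segments(
        nids[i],
        stats::setNames(as.logical(normal_alterations[i, ]),
                        colnames(normal_alterations)),
        config, genome, background = FALSE)$segments
    nsegments <- do.call(rbind, nseg_list)
    rownames(nsegments) <- NULL
    lm_normal <- summarize_loci(nsegments, annotation, genome)
    if (config$noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(lm_normal$values), 0,
                                   config$noise_sd),
                      nrow = nrow(lm_normal$values))
      lm_normal$values <- lm_normal$values + noise
    }
    normal <- list(
      segments = nsegments,
      locus_matrix = lm_normal,
      clinical = data.frame(sample_id = nids, group = ngroup,
                            ancestry_fraction = unname(nanc),
                            age = round(stats::rnorm(nn, 55, 10), 1),
                            stringsAsFactors = FALSE))
  }

  structure(
    list(segments = segments,
         locus_matrix = lm_tumor,
         clinical = clinical,
         annotation = annotation,
         normal = normal,
         truth = list(alterations = alterations,
                      segment_states = segment_states,
                      pga = true_pga,
                      fractions = fractions,
                      normal_alterations = normal_alterations)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$clinical), "tumor samples,",
      if (is.null(x$normal)) 0 else nrow(x$normal$clinical),
      "normal samples,", nrow(x$annotation), "annotated loci\n")
  invisible(x)
}

#' Toy methylation signature matrix
#'
#' Random reference beta values for a panel of cell types, reproducible by
#' seed. Synthetic stand-in for a purified-reference signature; columns
#' are distinct with probability one.
#'
#' @param n_cpgs Number of CpGs (rows).
#' @param cell_types Character vector of cell-type names.
#' @param seed Integer seed.
#' @return Matrix of reference beta values in \[0, 1\].
#' @export
toy_signature <- function(n_cpgs = 600,
                          cell_types = c("Treg", "Bcell", "CD8T", "CD4T",
                                         "NK", "Macrophage", "Neutrophil",
                                         "Eosinophil", "Endothelial",
                                         "Fibroblast"),
                          seed = 1L) {
  set.seed(seed)
  sig <- matrix(stats::runif(n_cpgs * length(cell_types)), n_cpgs,
                dimnames = list(sprintf("cg%06d", seq_len(n_cpgs)),
                                cell_types))
  sig
}

#' Mix signature columns into per-sample beta vectors
#'
#' Each sample's beta vector is the fraction-weighted combination of the
#' signature columns plus bounded Gaussian noise, clipped to \[0, 1\].
#'
#' @param fractions Samples x cell types matrix of non-negative fractions
#'   summing to one per row (e.g. `truth$fractions` from
#'   [simulate_cohort()]).
#' @param signature CpGs x cell types reference matrix (see
#'   [toy_signature()]); column names must match `fractions`.
#' @param noise_sd SD of additive noise on the beta scale (default 0).
#' @return Matrix of beta values, CpGs in rows, samples in columns.
#' @export
simulate_betas <- function(fractions, signature, noise_sd = 0) {
  stopifnot(is.matrix(fractions), is.matrix(signature))
  if (!identical(colnames(signature), colnames(fractions)))
    stop("fractions and signature must share identical cell-type columns")
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-6))
    stop("fractions must be non-negative and sum to 1 per sample")
  betas <- signature %*% t(fractions)
  if (noise_sd > 0)
    betas <- betas + matrix(stats::rnorm(length(betas), 0, noise_sd),
                            nrow = nrow(betas))
  betas[betas < 0] <- 0
  betas[betas > 1] <- 1
  betas
}
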