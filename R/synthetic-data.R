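## Synthetic paired GMV/genotype data with known latent structure: a cohort
## table emulating an ADHD case / unaffected-sibling / control study, smooth
## spatial gray-matter components, sparse block-structured SNP components,
## and a planted loading-level link between one SNP component and one or two
## GMV components whose strength differs by diagnostic group and age.

#' Cohort specification
#'
#' Defaults emulate the discovery sample: 341 unrelated adults aged 18-63 in
#' three diagnostic groups (167 ADHD, 47 unaffected siblings, 127 controls),
#' with group-specific sex, scan-site, medication and symptom distributions.
#' `family_mode = "sibling-families"` instead draws families (sizes from
#' `family_sizes` with probabilities `family_size_probs`) whose members
#' share site and ancestry exactly and whose ages fall within a 6-year
#' window, as in the adolescent replication sample.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param group_proportions Named fractions over ADHD/sibling/control,
#'   summing to 1.
#' @param family_mode `"unrelated"` or `"sibling-families"`.
#' @param family_sizes,family_size_probs Family-size distribution
#'   (sibling-families mode).
#' @param age_range Two-element numeric, years.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 341,
                        group_proportions = c(ADHD = 167, sibling = 47,
                                              control = 127) / 341,
                        family_mode = c("unrelated", "sibling-families"),
                        family_sizes = c(2, 3),
                        family_size_probs = c(0.7, 0.3),
                        age_range = c(18, 63),
                        seed = 1) {
  family_mode <- match.arg(family_mode)
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (length(group_proportions) != 3 ||
      abs(sum(group_proportions) - 1) > 1e-12)
    stopf("group_proportions must be 3 fractions summing to 1")
  if (is.null(names(group_proportions)))
    names(group_proportions) <- c("ADHD", "sibling", "control")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_proportions = group_proportions,
                 family_mode = family_mode, family_sizes = family_sizes,
                 family_size_probs = family_size_probs,
                 age_range = age_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

## Largest-remainder rounding of n * proportions to integer counts summing
## to n (exact proportions give exact counts).
.round_counts <- function(n, prop) {
  raw <- n * prop
  cnt <- floor(raw + 1e-9)
  left <- n - sum(cnt)
  if (left > 0) {
    frac <- raw - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(left)]
    cnt[add] <- cnt[add] + 1
  }
  as.integer(cnt)
}

## Group-conditional demographic rates (male fraction, Nijmegen-site
## fraction, stimulant-medication fraction) and symptom/digit-span moments
## for ADHD / sibling / control, patterned on the adult sample table.
.group_rates <- list(
  male = c(ADHD = 0.57, sibling = 0.51, control = 0.28),
  site = c(ADHD = 0.69, sibling = 0.45, control = 0.85),
  medication = c(ADHD = 0.47, sibling = 0, control = 0.008),
  inatt_mean = c(ADHD = 7.19, sibling = 1.72, control = 0.52),
  inatt_sd = c(ADHD = 1.74, sibling = 2.10, control = 1.18),
  hyper_mean = c(ADHD = 5.86, sibling = 1.51, control = 0.70),
  hyper_sd = c(ADHD = 2.37, sibling = 1.59, control = 1.00),
  dsf_mean = c(ADHD = 8.89, sibling = 9.00, control = 9.59),
  dsf_sd = c(ADHD = 1.98, sibling = 1.74, control = 1.93),
  dsb_mean = c(ADHD = 6.42, sibling = 5.96, control = 7.45),
  dsb_sd = c(ADHD = 2.31, sibling = 2.10, control = 2.04))

#' Generate a synthetic subject cohort
#'
#' @param spec A [cohort_spec()].
#' @return data.frame (class `spica_cohort`) with columns `subject_id`,
#'   `family_id`, `group`, `age`, `sex` (1 = male), `site` (1 = first
#'   site), `anc1`..`anc5`, `medication`, `inattention`, `hyperactivity`,
#'   `digit_forward`, `digit_backward`, `family_label` (1 = family with an
#'   affected member).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    cnt <- .round_counts(n, spec$group_proportions)
    groups <- sample(rep(names(spec$group_proportions), cnt))

    if (spec$family_mode == "unrelated") {
      family_id <- sprintf("F%04d", seq_len(n))
      age <- runif(n, spec$age_range[1], spec$age_range[2])
      site <- rbinom(n, 1, .group_rates$site[groups])
      anc <- matrix(rnorm(n * 5), n, 5)
    } else {
      sizes <- integer(0)
      while (sum(sizes) < n) {
        pick <- sample.int(length(spec$family_sizes), 1,
                           prob = spec$family_size_probs)
        sizes <- c(sizes, spec$family_sizes[pick])
      }
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
      sizes <- sizes[sizes > 0]
      fam <- rep(seq_along(sizes), sizes)
      family_id <- sprintf("F%04d", fam)
      base_age <- runif(length(sizes), spec$age_range[1],
                        max(spec$age_range[1],
                            spec$age_range[2] - 6))
      age <- pmin(base_age[fam] + runif(n, 0, 6), spec$age_range[2])
      fam_site <- rbinom(length(sizes), 1, 0.65)
      site <- fam_site[fam]
      fam_anc <- matrix(rnorm(length(sizes) * 5), length(sizes), 5)
      anc <- fam_anc[fam, , drop = FALSE]
    }
    sex <- rbinom(n, 1, .group_rates$male[groups])
    medication <- rbinom(n, 1, .group_rates$medication[groups])
    clamp09 <- function(v) pmin(pmax(round(v), 0), 9)
    inatt <- clamp09(rnorm(n, .group_rates$inatt_mean[groups],
                           .group_rates$inatt_sd[groups]))
    hyper <- clamp09(rnorm(n, .group_rates$hyper_mean[groups],
                           .group_rates$hyper_sd[groups]))
    dsf <- rnorm(n, .group_rates$dsf_mean[groups], .group_rates$dsf_sd[groups])
    dsb <- rnorm(n, .group_rates$dsb_mean[groups], .group_rates$dsb_sd[groups])
    affected <- tapply(groups %in% c("ADHD", "sibling"), family_id, any)
    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      family_id = family_id, group = groups, age = age, sex = sex,
      site = site, anc1 = anc[, 1], anc2 = anc[, 2], anc3 = anc[, 3],
      anc4 = anc[, 4], anc5 = anc[, 5], medication = medication,
      inattention = inatt, hyperactivity = hyper,
      digit_forward = dsf, digit_backward = dsb,
      family_label = as.integer(affected[family_id]),
      stringsAsFactors = FALSE)
    class(out) <- c("spica_cohort", "data.frame")
    out
  })
}

#' Generate smooth spatial component maps (Gaussian blobs)
#'
#' Each component is a nonnegative Gaussian blob on a 3-D voxel grid,
#' normalized to unit L2 norm. With `centers = NULL`, centers are spread
#' along the grid diagonal with a small seeded jitter, which keeps distinct
#' maps nearly orthogonal (pairwise |cosine| well under 0.3).
#'
#' @param grid_dims Integer 3-vector of grid dimensions.
#' @param k Number of maps.
#' @param centers Optional k x 3 matrix of blob centers (voxel units); must
#'   lie inside the grid.
#' @param widths Blob standard deviation(s) in voxels (recycled to k).
#' @param seed Integer seed (center jitter only).
#' @return List with `maps` (k x prod(grid_dims)), `centers`, `grid_dims`.
#' @export
generate_spatial_maps <- function(grid_dims = c(20, 20, 20), k = 3,
                                  centers = NULL, widths = 3, seed = 1) {
  stopifnot(length(grid_dims) == 3, k >= 1)
  widths <- rep_len(widths, k)
  if (is.null(centers)) {
    fr <- (seq_len(k)) / (k + 1)
    centers <- outer(fr, grid_dims) +
      with_seed(seed, matrix(runif(k * 3, -1, 1), k, 3))
    centers <- pmin(pmax(centers, 1.5),
                    matrix(grid_dims - 0.5, k, 3, byrow = TRUE))
  }
  centers <- matrix(as.numeric(centers), k, 3)
  if (any(centers < 1) || any(centers > rep(grid_dims, each = k)))
    stopf("blob center outside the grid")
  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                  y = seq_len(grid_dims[2]),
                                  z = seq_len(grid_dims[3])))
  maps <- matrix(0, k, nrow(coords))
  for (i in seq_len(k)) {
    d2 <- rowSums(sweep(coords, 2, centers[i, ], "-")^2)
    m <- exp(-d2 / (2 * widths[i]^2))
    maps[i, ] <- m / sqrt(sum(m^2))
  }
  list(maps = maps, centers = centers, grid_dims = grid_dims)
}

#' Generate sparse SNP component weights with LD-block structure
#'
#' SNP indices are partitioned into consecutive LD blocks of
#' `ld_block_size`. Each component's active set is a disjoint union of
#' whole blocks (truncated to exactly `n_active` SNPs). Weights are
#' coherent within a block (one sign and base magnitude per block, small
#' per-SNP magnitude jitter) and random across blocks: SNPs in LD tag the
#' same underlying signal, so correlated SNPs load together on the same
#' component with consistent sign.
#'
#' @param n_snps Total SNPs.
#' @param k Number of components.
#' @param n_active Nonzeros per component (`k * n_active <= n_snps`).
#' @param ld_block_size SNPs per LD block.
#' @param seed Integer seed.
#' @return List with `weights` (k x n_snps), `blocks` (block index per
#'   SNP), `active` (list of active index vectors).
#' @export
generate_sparse_snp_weights <- function(n_snps, k, n_active = 30,
                                        ld_block_size = 10, seed = 1) {
  if (n_active * k > n_snps)
    stopf("infeasible sparsity: %d active x %d components > %d SNPs",
          n_active, k, n_snps)
  blocks <- ceiling(seq_len(n_snps) / ld_block_size)
  n_blocks <- max(blocks)
  bpc <- ceiling(n_active / ld_block_size)
  if (bpc * k > n_blocks)
    stopf("not enough LD blocks (%d) for %d components x %d blocks each",
          n_blocks, k, bpc)
  with_seed(seed, {
    free <- sample(n_blocks)
    W <- matrix(0, k, n_snps)
    active <- vector("list", k)
    for (i in seq_len(k)) {
      myblocks <- free[seq_len(bpc) + (i - 1) * bpc]
      base <- setNames(sample(c(-1, 1), bpc, TRUE) * runif(bpc, 0.6, 1.4),
                       myblocks)
      idx <- which(blocks %in% myblocks)[seq_len(n_active)]
      W[i, idx] <- base[as.character(blocks[idx])] *
        runif(n_active, 0.8, 1.2)
      active[[i]] <- idx
    }
    list(weights = W, blocks = blocks, active = active)
  })
}

#' Cross-modal link specification
#'
#' @param pairs Two-column matrix (or length-2 vector) of
#'   (gmv component, snp component) indices.
#' @param target_r_by_group Named correlations (ADHD/sibling/control) of the
#'   linked loading pair within each group; each |r| < 1. The defaults
#'   mirror a link that is strong in siblings and cases and weak in
#'   controls.
#' @param age_slope Optional per-year multiplicative ramp of the link
#'   strength around the age midpoint (0 = no age modulation); the
#'   per-subject correlation is clipped to (-0.95, 0.95).
#' @return A `link_spec` list.
#' @export
link_spec <- function(pairs = cbind(1, 1),
                      target_r_by_group = c(ADHD = 0.6, sibling = 0.7,
                                            control = 0.3),
                      age_slope = 0) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(abs(target_r_by_group) >= 1))
    stopf("|target_r| must be < 1")
  structure(list(pairs = pairs, target_r_by_group = target_r_by_group,
                 age_slope = age_slope), class = "link_spec")
}

## Pilot calibration of the genotype effect size: smallest beta on a grid
## whose simulated dosage-loading correlation (at f = 0.3 and the typical
## relative weight `w_rel`) reaches `target_cor`, medianed over 3 pilot
## draws to stabilize the choice.
.calibrate_beta <- function(target_cor = 0.75, seed = 1, w_rel = 1) {
  with_seed(seed + 777L, {
    for (beta in seq(0.25, 8, by = 0.25)) {
      cors <- vapply(1:3, function(i) {
        s <- rnorm(1000)
        f <- plogis(qlogis(0.3) + beta * w_rel * s)
        cor(s, rbinom(1000, 2, f))
      }, numeric(1))
      if (median(cors) >= target_cor) return(beta)
    }
    8
  })
}

#' Simulate linked GMV and genotype data for a cohort
#'
#' The gray-matter block is \eqn{X_g = B + A_g S_g + E}: a fixed smooth
#' baseline B (a broad central envelope peaking at `baseline_peak`, the
#' "brain", so mean-GMV masking at 0.2 behaves as on real tissue maps) plus
#' smooth spatial components with Gaussian voxel noise. Genotype dosages stay valid
#' \{0,1,2\}: each SNP j of subject i is Binomial(2, f_ij) with
#' \eqn{\mathrm{logit}(f_{ij}) = \mathrm{logit}(f_j) + \beta\,a_i w_j},
#' where \eqn{a_i} is the subject's loading on the component owning the
#' SNP's LD block and \eqn{\beta} is pilot-calibrated so the dosage-loading
#' correlation is material. SNPs within an LD block are allele-level copies
#' of a block root with per-allele flip probability `ld_flip`. For each
#' linked pair, the two loading columns are drawn from a bivariate normal
#' whose correlation is the subject's group target (optionally ramped in
#' age).
#'
#' @param cohort A `spica_cohort` data.frame.
#' @param maps Output of [generate_spatial_maps()].
#' @param snp_weights Output of [generate_sparse_snp_weights()].
#' @param link A [link_spec()].
#' @param noise_sd Voxel noise standard deviation (components have unit L2
#'   norm and unit-variance loadings, so 0.01 keeps the planted subspace
#'   clearly above the noise floor).
#' @param baseline_peak Peak of the smooth baseline envelope (0 disables
#'   it); width is 0.45 of the grid extent.
#' @param ld_flip Per-allele flip probability within an LD block.
#' @param dosage_cor Pilot target for the dosage-loading correlation.
#' @param seed Integer seed.
#' @return List with `X_gmv` (subjects x voxels), `X_snp` (subjects x SNPs
#'   dosages), `snp_meta` (snp_id, chrom, pos, gwas_p; active SNPs carry
#'   small GWAS p-values), and `truth` (planted maps, weights, loadings,
#'   link, allele frequencies, blocks).
#' @export
simulate_linked_data <- function(cohort, maps, snp_weights, link,
                                 noise_sd = 0.01, ld_flip = 0.15,
                                 dosage_cor = 0.75, baseline_peak = 0.5,
                                 seed = 1) {
  stopifnot(inherits(link, "link_spec"))
  n <- nrow(cohort)
  S_g <- maps$maps
  W_s <- snp_weights$weights
  blocks <- snp_weights$blocks
  k_g <- nrow(S_g); k_s <- nrow(W_s); n_snps <- ncol(W_s)
  if (any(link$pairs[, 1] > k_g) || any(link$pairs[, 2] > k_s))
    stopf("link references a nonexistent component")
  wnz <- abs(W_s[W_s != 0])
  beta <- .calibrate_beta(dosage_cor, seed,
                          w_rel = median(wnz) / max(wnz))

  with_seed(seed, {
    A_g <- matrix(rnorm(n * k_g), n, k_g)
    A_s <- matrix(rnorm(n * k_s), n, k_s)
    age_mid <- mean(range(cohort$age))
    for (pr in seq_len(nrow(link$pairs))) {
      gi <- link$pairs[pr, 1]; si <- link$pairs[pr, 2]
      r_i <- link$target_r_by_group[cohort$group] *
        (1 + link$age_slope * (cohort$age - age_mid))
      r_i <- pmin(pmax(r_i, -0.95), 0.95)
      z1 <- rnorm(n); z2 <- rnorm(n)
      A_g[, gi] <- z1
      A_s[, si] <- r_i * z1 + sqrt(1 - r_i^2) * z2
    }

    baseline <- numeric(ncol(S_g))
    if (baseline_peak > 0 && !is.null(maps$grid_dims)) {
      gd <- maps$grid_dims
      coords <- as.matrix(expand.grid(x = seq_len(gd[1]), y = seq_len(gd[2]),
                                      z = seq_len(gd[3])))
      ctr <- (gd + 1) / 2
      d2 <- rowSums(sweep(coords, 2, ctr, "-")^2)
      baseline <- baseline_peak * exp(-d2 / (2 * (0.45 * mean(gd))^2))
    }
    X_gmv <- matrix(baseline, n, ncol(S_g), byrow = TRUE) +
      A_g %*% S_g + noise_sd * matrix(rnorm(n * ncol(S_g)), n)

    ## per-block allele frequency; the component owning a block (if any)
    ## modulates its root's frequency through the logistic link
    n_blocks <- max(blocks)
    f_block <- runif(n_blocks, 0.05, 0.5)
    f_snp <- f_block[blocks]
    owner <- integer(n_snps)                     # component per SNP (0 none)
    for (i in seq_len(k_s)) owner[snp_weights$active[[i]]] <- i
    wmax <- max(abs(W_s))
    X_snp <- matrix(0L, n, n_snps)
    for (b in seq_len(n_blocks)) {
      idx <- which(blocks == b)
      fb <- f_block[b]
      ## block root alleles, frequency modulated by the owning component
      own_b <- owner[idx]
      lead <- if (any(own_b > 0)) idx[which(own_b > 0)[1]] else idx[1]
      eta <- if (owner[lead] > 0)
        qlogis(fb) + beta * A_s[, owner[lead]] * W_s[owner[lead], lead] / wmax
      else rep(qlogis(fb), n)
      f_root <- plogis(eta)
      a1 <- rbinom(n, 1, f_root)
      a2 <- rbinom(n, 1, f_root)
      for (j in idx) {
        fj <- if (owner[j] > 0)
          plogis(qlogis(fb) + beta * A_s[, owner[j]] * W_s[owner[j], j] / wmax)
        else f_root
        b1 <- ifelse(runif(n) < ld_flip, rbinom(n, 1, fj), a1)
        b2 <- ifelse(runif(n) < ld_flip, rbinom(n, 1, fj), a2)
        X_snp[, j] <- b1 + b2
      }
    }

    gwas_p <- ifelse(owner > 0, 10^-runif(n_snps, 3.2, 8),
                     10^-runif(n_snps, 0, 5))
    snp_meta <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(n_snps)),
      chrom = 1L + (blocks - 1L) %/% max(1L, ceiling(n_blocks / 22)),
      pos = as.integer(seq_len(n_snps)) * 1000L,
      gwas_p = gwas_p, block = blocks, owner = owner,
      stringsAsFactors = FALSE)

    rownames(X_gmv) <- rownames(X_snp) <- cohort$subject_id
    colnames(X_snp) <- snp_meta$snp_id
    list(X_gmv = X_gmv, X_snp = X_snp, snp_meta = snp_meta,
         truth = list(gmv_maps = S_g, snp_weights = W_s, A_g = A_g,
                      A_s = A_s, link = link, allele_freqs = f_snp,
                      blocks = blocks, beta = beta, noise_sd = noise_sd,
                      baseline = baseline))
  })
}
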