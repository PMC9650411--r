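#' Specify one planted co-expression module
#'
#' A module is a block of lncRNAs and mRNAs driven by a shared latent factor
#' `f ~ N(0,1)` with loading `factor_loading` (alpha).  If
#' `mirna_loading` (beta) is positive the module is a true miRNA sponge
#' module: `n_shared_mirna` miRNAs `u_k ~ N(0,1)` are subtracted from every
#' member transcript with weight beta (miRNAs repress their targets, so
#' ceRNA pairs correlate positively with each other and negatively with the
#' shared miRNAs).  `mirna_loading = 0` defines a decoy module: it is
#' co-expressed, and its miRNAs still target its members in the target
#' matrix, but miRNA expression does not mediate the lncRNA-mRNA
#' correlation.
#'
#' @param n_lncrna,n_mrna Number of member lncRNAs / mRNAs (each >= 1).
#' @param n_shared_mirna Number of miRNAs targeting all module members.
#' @param factor_loading Loading alpha of the latent module factor.
#' @param mirna_loading Loading beta of the shared-miRNA term; 0 for decoys.
#' @return A `module_spec` list with an `is_sponge` flag
#'   (`mirna_loading > 0` and `n_shared_mirna >= 1`).
#' @export
module_spec <- function(n_lncrna, n_mrna, n_shared_mirna = 0,
                        factor_loading = 1, mirna_loading = 0) {
  if (n_lncrna < 1 || n_mrna < 1)
    stop("modules need at least one lncRNA and one mRNA", call. = FALSE)
  if (n_shared_mirna < 0)
    stop("n_shared_mirna must be non-negative", call. = FALSE)
  if (mirna_loading < 0)
    stop("mirna_loading must be non-negative", call. = FALSE)
  if (mirna_loading > 0 && n_shared_mirna < 1)
    stop("mirna_loading > 0 requires n_shared_mirna >= 1", call. = FALSE)
  structure(
    list(n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
         n_shared_mirna = as.integer(n_shared_mirna),
         factor_loading = factor_loading, mirna_loading = mirna_loading,
         is_sponge = mirna_loading > 0 && n_shared_mirna >= 1),
    class = "module_spec"
  )
}

#' Specify a synthetic expression study
#'
#' @param n_samples Number of samples.
#' @param n_mrna,n_lncrna,n_mirna Totals per RNA class; genes not claimed by
#'   a module are background (pure noise).
#' @param modules List of [module_spec()] objects.
#' @param background_target_density Probability of an independent
#'   miRNA-target edge outside the planted module edges.
#' @param noise_sd Standard deviation of the transcript-level noise; also
#'   the scale of background mRNA/lncRNA expression.
#' @param baseline Constant added to every expression value so the bundle
#'   emulates post-normalization log-scale data (positive for expressed
#'   genes); shift-invariant statistics downstream are unaffected.
#' @param case_fraction Expected fraction of case samples.
#' @param biomarker_effects Named numeric vector: lncRNA id -> expression
#'   shift added to case samples, in units of `noise_sd`.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples, n_mrna, n_lncrna, n_mirna,
                            modules,
                            background_target_density = 0.001,
                            noise_sd = 1,
                            baseline = 5,
                            case_fraction = 0.5,
                            biomarker_effects = numeric(),
                            seed = 1L) {
  stopifnot(n_samples >= 1, n_mrna >= 1, n_lncrna >= 1, n_mirna >= 1)
  if (background_target_density < 0 || background_target_density > 1)
    stop("background_target_density must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0, 1)", call. = FALSE)
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "module_spec")) do.call(module_spec, m) else m
  })
  if (sum(vapply(modules, `[[`, 1L, "n_lncrna")) > n_lncrna)
    stop("module lncRNA counts exceed n_lncrna", call. = FALSE)
  if (sum(vapply(modules, `[[`, 1L, "n_mrna")) > n_mrna)
    stop("module mRNA counts exceed n_mrna", call. = FALSE)
  if (sum(vapply(modules, `[[`, 1L, "n_shared_mirna")) > n_mirna)
    stop("module shared-miRNA counts exceed n_mirna", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), n_mrna = as.integer(n_mrna),
         n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
         modules = modules,
         background_target_density = background_target_density,
         noise_sd = noise_sd, baseline = baseline,
         case_fraction = case_fraction,
         biomarker_effects = biomarker_effects, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Default synthetic study: four sponge modules, three decoys
#'
#' Desk-scale stand-in for a joint brain-transcriptome bundle: 150 samples,
#' 2000 mRNAs, 300 lncRNAs and 35 miRNAs.  Four true sponge modules
#' (10 lncRNAs + 60 mRNAs, 3 shared miRNAs, alpha = 1, beta = 0.8) and
#' three decoys with matched within-module correlation (alpha = 1.7,
#' beta = 0), so decoys are indistinguishable at the co-expression stage and
#' can only be rejected by the sensitivity canonical correlation.  Two
#' background lncRNAs carry case-control shifts of 2 and 1 noise-SD units
#' as planted diagnostic biomarkers.
#'
#' @param seed Integer seed.
#' @return A `simulation_spec`.
#' @export
default_simulation_spec <- function(seed = 1L) {
  sponge <- module_spec(n_lncrna = 10, n_mrna = 60, n_shared_mirna = 3,
                        factor_loading = 1, mirna_loading = 0.8)
  decoy <- module_spec(n_lncrna = 10, n_mrna = 60, n_shared_mirna = 3,
                       factor_loading = 1.7, mirna_loading = 0)
  simulation_spec(
    n_samples = 150, n_mrna = 2000, n_lncrna = 300, n_mirna = 35,
    modules = c(rep(list(sponge), 4), rep(list(decoy), 3)),
    background_target_density = 0.001,
    noise_sd = 1, case_fraction = 0.5,
    biomarker_effects = c(lnc_0291 = 2, lnc_0292 = 1),
    seed = seed
  )
}

#' Generate a synthetic expression bundle with known ground truth
#'
#' Generative model, per sample s: each module m has a latent factor
#' `f_m(s) ~ N(0,1)`; each of its shared miRNAs k has `u_k(s) ~ N(0,1)`.
#' Member transcripts (lncRNA or mRNA) are
#' `alpha_m * f_m(s) - beta_m * sum_k u_k(s) + eps`,
#' `eps ~ N(0, noise_sd^2)`; shared miRNA expression is `u_k(s)` itself;
#' background genes are pure noise (mRNA/lncRNA at `noise_sd`, miRNA at
#' unit SD, matching the planted miRNA scale).  The target matrix contains
#' the planted edges from each module's miRNAs to all of that module's
#' members, plus independent Bernoulli background edges.  Biomarker lncRNAs
#' get `effect * noise_sd` added on case samples.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `bundle` ([expression_bundle()]),
#'   `targets` (a `target_matrix`: binary miRNA x mRNA and miRNA x lncRNA
#'   incidence matrices) and `truth` (module membership, per-module
#'   parameters and flags, planted miRNA ids, biomarkers).
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  mrna_ids <- sprintf("mRNA_%04d", seq_len(spec$n_mrna))
  lnc_ids <- sprintf("lnc_%04d", seq_len(spec$n_lncrna))
  mir_ids <- sprintf("miR_%03d", seq_len(spec$n_mirna))

  with_seed(spec$seed, {
    k <- length(spec$modules)
    f <- matrix(stats::rnorm(k * n), nrow = k, ncol = n)
    u <- lapply(spec$modules, function(m)
      matrix(stats::rnorm(m$n_shared_mirna * n), nrow = m$n_shared_mirna,
             ncol = n))

    mrna <- matrix(stats::rnorm(spec$n_mrna * n, sd = spec$noise_sd),
                   nrow = spec$n_mrna, dimnames = list(mrna_ids, samples))
    lncrna <- matrix(stats::rnorm(spec$n_lncrna * n, sd = spec$noise_sd),
                     nrow = spec$n_lncrna, dimnames = list(lnc_ids, samples))
    mirna <- matrix(stats::rnorm(spec$n_mirna * n),
                    nrow = spec$n_mirna, dimnames = list(mir_ids, samples))

    membership <- stats::setNames(integer(spec$n_mrna + spec$n_lncrna),
                                  c(mrna_ids, lnc_ids))
    modules <- vector("list", k)
    next_mr <- 1L; next_lnc <- 1L; next_mir <- 1L
    for (i in seq_len(k)) {
      m <- spec$modules[[i]]
      mr <- mrna_ids[seq(next_mr, length.out = m$n_mrna)]
      lnc <- lnc_ids[seq(next_lnc, length.out = m$n_lncrna)]
      mir <- if (m$n_shared_mirna > 0)
        mir_ids[seq(next_mir, length.out = m$n_shared_mirna)] else character()
      next_mr <- next_mr + m$n_mrna
      next_lnc <- next_lnc + m$n_lncrna
      next_mir <- next_mir + m$n_shared_mirna

      signal <- m$factor_loading * f[i, ]
      if (m$n_shared_mirna > 0) {
        signal <- signal - m$mirna_loading * colSums(u[[i]])
        mirna[mir, ] <- u[[i]]
      }
      mrna[mr, ] <- sweep(mrna[mr, , drop = FALSE], 2, signal, `+`)
      lncrna[lnc, ] <- sweep(lncrna[lnc, , drop = FALSE], 2, signal, `+`)
      membership[c(mr, lnc)] <- i
      modules[[i]] <- list(id = i, lncrna = lnc, mrna = mr, mirna = mir,
                           factor_loading = m$factor_loading,
                           mirna_loading = m$mirna_loading,
                           is_sponge = m$is_sponge)
    }

    traits <- data.frame(
      sample_id = samples,
      diagnosis = sample(1:3, n, replace = TRUE),
      case = stats::rbinom(n, 1, spec$case_fraction),
      stringsAsFactors = FALSE
    )

    bio <- spec$biomarker_effects
    if (length(bio)) {
      missing <- setdiff(names(bio), lnc_ids)
      if (length(missing))
        stop("biomarker ids not among lncRNAs: ",
             paste(missing, collapse = ", "), call. = FALSE)
      for (id in names(bio)) {
        shift <- bio[[id]] * spec$noise_sd
        lncrna[id, traits$case == 1] <- lncrna[id, traits$case == 1] + shift
      }
    }

    t_mr <- matrix(stats::rbinom(spec$n_mirna * spec$n_mrna, 1,
                                 spec$background_target_density),
                   nrow = spec$n_mirna, dimnames = list(mir_ids, mrna_ids))
    t_lnc <- matrix(stats::rbinom(spec$n_mirna * spec$n_lncrna, 1,
                                  spec$background_target_density),
                    nrow = spec$n_mirna, dimnames = list(mir_ids, lnc_ids))
    for (mod in modules) {
      if (length(mod$mirna)) {
        t_mr[mod$mirna, mod$mrna] <- 1L
        t_lnc[mod$mirna, mod$lncrna] <- 1L
      }
    }

    bundle <- expression_bundle(mrna + spec$baseline,
                                lncrna + spec$baseline,
                                mirna + spec$baseline, traits)
    targets <- target_matrix(t_mr, t_lnc)
    truth <- structure(
      list(membership = membership, modules = modules,
           biomarkers = bio, noise_sd = spec$noise_sd,
           baseline = spec$baseline,
           case_fraction = spec$case_fraction,
           n_samples = n, seed = spec$seed),
      class = "ground_truth"
    )
    list(bundle = bundle, targets = targets, truth = truth)
  })
}

#' Binary miRNA-target incidence, split by target class
#'
#' @param mirna_mrna Binary miRNA x mRNA matrix (dimnames required).
#' @param mirna_lncrna Binary miRNA x lncRNA matrix (same miRNA rows).
#' @return A `target_matrix` object.
#' @export
target_matrix <- function(mirna_mrna, mirna_lncrna) {
  stopifnot(is.matrix(mirna_mrna), is.matrix(mirna_lncrna),
            identical(rownames(mirna_mrna), rownames(mirna_lncrna)))
  if (!all(mirna_mrna %in% c(0, 1)) || !all(mirna_lncrna %in% c(0, 1)))
    stop("target matrices must be binary", call. = FALSE)
  structure(list(mirna_mrna = mirna_mrna, mirna_lncrna = mirna_lncrna),
            class = "target_matrix")
}

#' Generate a perturbed test dataset for preservation analysis
#'
#' Modules listed in `preserve` are regenerated from the same generative law
#' with fresh latent factors, miRNA factors and noise (co-expression
#' structure preserved, realization new).  All other planted modules have
#' each member gene's expression independently permuted across samples
#' (structure destroyed, marginals kept).  Background genes are redrawn as
#' fresh noise.  Gene ids and counts are unchanged.
#'
#' @param bundle The reference bundle from [generate_bundle()].
#' @param truth Its `ground_truth`.
#' @param preserve Integer vector of module ids to preserve (may be empty).
#' @param seed Integer seed.
#' @param n_samples Sample count of the test set; defaults to the reference
#'   count.  If different, destroyed-module rows are resampled from the
#'   reference values instead of permuted.
#' @return A new `expression_bundle`.
#' @export
generate_test_dataset <- function(bundle, truth, preserve, seed,
                                  n_samples = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"),
            inherits(truth, "ground_truth"))
  ids <- vapply(truth$modules, `[[`, 1L, "id")
  unknown <- setdiff(preserve, ids)
  if (length(unknown))
    stop("unknown module id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n_ref <- ncol(bundle$mrna)
  if (is.null(n_samples)) n_samples <- n_ref
  samples <- if (n_samples == n_ref) colnames(bundle$mrna) else
    sprintf("T%03d", seq_len(n_samples))

  with_seed(seed, {
    redraw_row <- function(x) {
      if (n_samples == n_ref) sample(x) else
        sample(x, n_samples, replace = TRUE)
    }
    mrna <- matrix(stats::rnorm(nrow(bundle$mrna) * n_samples,
                                sd = truth$noise_sd),
                   nrow = nrow(bundle$mrna),
                   dimnames = list(rownames(bundle$mrna), samples))
    lncrna <- matrix(stats::rnorm(nrow(bundle$lncrna) * n_samples,
                                  sd = truth$noise_sd),
                     nrow = nrow(bundle$lncrna),
                     dimnames = list(rownames(bundle$lncrna), samples))
    mirna <- matrix(stats::rnorm(nrow(bundle$mirna) * n_samples),
                    nrow = nrow(bundle$mirna),
                    dimnames = list(rownames(bundle$mirna), samples))

    destroyed <- list(mrna = character(), lncrna = character(),
                      mirna = character())
    for (mod in truth$modules) {
      if (mod$id %in% preserve) {
        fm <- stats::rnorm(n_samples)
        signal <- mod$factor_loading * fm
        if (length(mod$mirna)) {
          um <- matrix(stats::rnorm(length(mod$mirna) * n_samples),
                       nrow = length(mod$mirna))
          signal <- signal - mod$mirna_loading * colSums(um)
          mirna[mod$mirna, ] <- um
        }
        mrna[mod$mrna, ] <-
          sweep(mrna[mod$mrna, , drop = FALSE], 2, signal, `+`)
        lncrna[mod$lncrna, ] <-
          sweep(lncrna[mod$lncrna, , drop = FALSE], 2, signal, `+`)
      } else {
        for (g in mod$mrna) mrna[g, ] <- redraw_row(bundle$mrna[g, ])
        for (g in mod$lncrna) lncrna[g, ] <- redraw_row(bundle$lncrna[g, ])
        for (g in mod$mirna) mirna[g, ] <- redraw_row(bundle$mirna[g, ])
        destroyed$mrna <- c(destroyed$mrna, mod$mrna)
        destroyed$lncrna <- c(destroyed$lncrna, mod$lncrna)
        destroyed$mirna <- c(destroyed$mirna, mod$mirna)
      }
    }

    traits <- data.frame(
      sample_id = samples,
      diagnosis = sample(1:3, n_samples, replace = TRUE),
      case = stats::rbinom(n_samples, 1, truth$case_fraction),
      stringsAsFactors = FALSE
    )
    bio <- truth$biomarkers
    if (length(bio)) {
      for (id in names(bio)) {
        shift <- bio[[id]] * truth$noise_sd
        lncrna[id, traits$case == 1] <- lncrna[id, traits$case == 1] + shift
      }
    }
    base <- truth$baseline
    # destroyed rows were resampled from already-baselined reference values
    fresh_m <- setdiff(rownames(mrna), destroyed$mrna)
    fresh_l <- setdiff(rownames(lncrna), destroyed$lncrna)
    fresh_i <- setdiff(rownames(mirna), destroyed$mirna)
    mrna[fresh_m, ] <- mrna[fresh_m, ] + base
    lncrna[fresh_l, ] <- lncrna[fresh_l, ] + base
    mirna[fresh_i, ] <- mirna[fresh_i, ] + base
    expression_bundle(mrna, lncrna, mirna, traits)
  })
}
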