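#' Read a genes x samples expression TSV
#'
#' Expected format: header row of sample ids, first column gene ids,
#' remaining cells finite numbers.  Duplicate gene ids, non-numeric cells
#' and ragged rows are rejected with the offending line number.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  n <- length(samples)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- character(length(rows))
  m <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n + 1)
      stop("ragged row at line ", i + 1, " of ", path, ": expected ",
           n + 1, " fields, got ", length(r), call. = FALSE)
    ids[i] <- r[1]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (any(!is.finite(vals)))
      stop("non-numeric or non-finite value at line ", i + 1, " of ",
           path, call. = FALSE)
    m[i, ] <- vals
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene id '", dup[1], "' at line ",
         which(ids == dup[1])[2] + 1, " of ", path, call. = FALSE)
  dimnames(m) <- list(ids, samples)
  m
}

#' Write a genes x samples matrix as TSV
#'
#' First column `gene_id`, header row of sample ids; round-trips through
#' [read_expression_tsv()].
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an expression bundle directory
#'
#' The directory holds `mrna.tsv`, `lncrna.tsv`, `mirna.tsv` (genes x
#' samples) and `traits.tsv` (sample_id, diagnosis, case).
#'
#' @param bundle An [expression_bundle()].
#' @param dir Directory (created if needed).
#' @return The directory (write) / the bundle (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in c("mrna", "lncrna", "mirna"))
    write_expression_tsv(bundle[[cls]], file.path(dir,
                                                  paste0(cls, ".tsv")))
  utils::write.table(bundle$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  traits <- utils::read.delim(file.path(dir, "traits.tsv"),
                              stringsAsFactors = FALSE)
  traits$sample_id <- as.character(traits$sample_id)
  expression_bundle(
    mrna = read_expression_tsv(file.path(dir, "mrna.tsv")),
    lncrna = read_expression_tsv(file.path(dir, "lncrna.tsv")),
    mirna = read_expression_tsv(file.path(dir, "mirna.tsv")),
    traits = traits
  )
}

#' Read a miRNA-target edge list into a target matrix
#'
#' Two-column TSV (miRNA id, target id), with or without a header.  Edges
#' whose miRNA is not in `known_mirnas` or whose target is in neither gene
#' list are skipped (counted, not fatal); duplicate edges collapse.
#'
#' @param path Edge-list TSV.
#' @param known_mirnas miRNA ids of the expression data.
#' @param known_mrnas,known_lncrnas Gene ids of the expression data.
#' @return A [target_matrix()] with attribute `"skipped"` (number of edges
#'   dropped for unknown ids).
#' @export
read_target_edges <- function(path, known_mirnas, known_mrnas,
                              known_lncrnas) {
  if (!file.exists(path))
    stop("miRNA-target edge list not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("edge list needs at least 2 columns: ", path, call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("mirna", "target")
  if (identical(tolower(df$mirna[1]), "mirna")) df <- df[-1, , drop = FALSE]
  df <- unique(df)
  ok_mir <- df$mirna %in% known_mirnas
  is_mr <- df$target %in% known_mrnas
  is_lnc <- df$target %in% known_lncrnas
  keep <- ok_mir & (is_mr | is_lnc)
  skipped <- sum(!keep)
  if (skipped)
    message(skipped, " edge(s) with unknown ids skipped from ", path)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no usable edges in ", path, call. = FALSE)
  t_mr <- matrix(0L, length(known_mirnas), length(known_mrnas),
                 dimnames = list(known_mirnas, known_mrnas))
  t_lnc <- matrix(0L, length(known_mirnas), length(known_lncrnas),
                  dimnames = list(known_mirnas, known_lncrnas))
  mr_edges <- df[df$target %in% known_mrnas, , drop = FALSE]
  lnc_edges <- df[df$target %in% known_lncrnas, , drop = FALSE]
  t_mr[cbind(mr_edges$mirna, mr_edges$target)] <- 1L
  t_lnc[cbind(lnc_edges$mirna, lnc_edges$target)] <- 1L
  tm <- target_matrix(t_mr, t_lnc)
  attr(tm, "skipped") <- skipped
  tm
}

#' Write a target matrix as a two-column edge list
#'
#' @param targets A [target_matrix()].
#' @param path Output TSV path.
#' @export
write_target_edges <- function(targets, path) {
  edges <- rbind(
    which(targets$mirna_mrna == 1, arr.ind = TRUE),
    which(targets$mirna_lncrna == 1, arr.ind = TRUE)
  )
  df <- data.frame(
    mirna = c(rownames(targets$mirna_mrna)[
      which(targets$mirna_mrna == 1, arr.ind = TRUE)[, 1]],
      rownames(targets$mirna_lncrna)[
        which(targets$mirna_lncrna == 1, arr.ind = TRUE)[, 1]]),
    target = c(colnames(targets$mirna_mrna)[
      which(targets$mirna_mrna == 1, arr.ind = TRUE)[, 2]],
      colnames(targets$mirna_lncrna)[
        which(targets$mirna_lncrna == 1, arr.ind = TRUE)[, 2]])
  )
  df <- df[order(df$mirna, df$target), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a validated pipeline configuration
#'
#' Defaults follow the standard protocol for this analysis family: 50%
#' expression filter,
#' connectivity-Z outlier cutoff -2, soft power chosen by scale-free fit
#' (R^2 > 0.8) from candidates 1..20, minimum module size 50, at least 3
#' lncRNAs per candidate module, sharing and adjusted-p thresholds 0.05,
#' 200 preservation permutations.  `n_null` defaults to 1e6 sampled null
#' datasets; reduce it for desk-scale runs.
#'
#' @param ... Overrides of the defaults listed above.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_fraction = 0.5, expression_floor = 0, z_cutoff = -2,
    power = "auto", powers = 1:20, r2_cutoff = 0.8,
    min_module_size = 50, cut_fraction = 0.99,
    min_lncrna = 3, sharing_alpha = 0.05, adj_alpha = 0.05,
    n_null = 1e6, dim_cap = NULL, n_perm = 200,
    auc_cutoff = 0.7, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$min_fraction > 0, cfg$min_fraction <= 1,
            cfg$min_module_size >= 1, cfg$n_null >= 100,
            cfg$n_perm >= 10, cfg$auc_cutoff > 0, cfg$auc_cutoff < 1)
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full sponge-module pipeline
#'
#' preprocess (expression filter + outlier removal) -> signed network,
#' module detection, eigengenes, module-trait correlation -> sponge-module
#' identification; optionally module preservation on a test bundle and ROC
#' biomarker screening of flagged-module lncRNAs.  All result tables are
#' written under `out_dir` together with a JSON run manifest (parameters,
#' seed, per-stage counts).
#'
#' @param bundle An [expression_bundle()] (or a bundle directory path).
#' @param targets A [target_matrix()] (or an edge-list TSV path).
#' @param config A [run_config()].
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param test_bundle Optional test `expression_bundle` (or directory) for
#'   preservation analysis.
#' @param roc Logical: screen lncRNAs of flagged modules by AUC.
#' @return List with `bundle` (preprocessed), `power`, `modules`,
#'   `eigengenes`, `trait_correlation`, `sponge`, optional `preservation`
#'   and `roc`, and `manifest`.
#' @export
run_pipeline <- function(bundle, targets, config = run_config(),
                         out_dir = NULL, test_bundle = NULL, roc = TRUE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  if (is.character(test_bundle)) test_bundle <- read_bundle(test_bundle)
  if (is.character(targets))
    targets <- read_target_edges(targets, rownames(bundle$mirna),
                                 rownames(bundle$mrna),
                                 rownames(bundle$lncrna))
  stopifnot(inherits(config, "run_config"))
  n_samples0 <- ncol(bundle$mrna)
  n_genes0 <- nrow(bundle$mrna) + nrow(bundle$lncrna)

  # heuristic raw-count check: already-normalized matrices expected
  vals <- bundle$mrna
  if (all(vals == round(vals)) && max(vals) > 1e4)
    warning("expression values look like raw counts; the pipeline ",
            "expects normalized (log-scale) matrices", call. = FALSE)

  bundle <- filter_low_expression(bundle, config$min_fraction,
                                  config$expression_floor)
  bundle <- remove_outliers(bundle, config$z_cutoff)

  expr <- rbind(bundle$mrna, bundle$lncrna)  # miRNAs never enter the network
  sim <- signed_similarity(expr)
  if (identical(config$power, "auto")) {
    pk <- pick_soft_threshold(sim, config$powers, config$r2_cutoff)
    power <- pk$power
    fits <- pk$fits
  } else {
    power <- as.numeric(config$power)
    fits <- NULL
  }
  tom <- topological_overlap(soft_adjacency(sim, power))
  modules <- cut_modules(tom, config$min_module_size, config$cut_fraction)
  me <- module_eigengene(expr, modules)
  trait_cor <- module_trait_correlation(me$eigengenes, bundle$traits)

  sponge <- identify_sponge_modules(
    bundle, modules, targets,
    min_lncrna = config$min_lncrna, sharing_alpha = config$sharing_alpha,
    adj_alpha = config$adj_alpha, n_null = config$n_null,
    seed = stage_seed(config$seed, "null"), dim_cap = config$dim_cap
  )

  preservation <- NULL
  if (!is.null(test_bundle)) {
    test_expr <- rbind(test_bundle$mrna, test_bundle$lncrna)
    preservation <- preservation_zsummary(expr, test_expr, modules, power,
                                          n_perm = config$n_perm,
                                          seed = config$seed)
  }

  roc_table <- NULL
  if (roc && nrow(sponge$summary) && any(sponge$summary$is_sponge)) {
    flagged <- as.character(
      sponge$summary$module[sponge$summary$is_sponge])
    cands <- unique(unlist(lapply(sponge$members[flagged], `[[`,
                                  "lncrna")))
    roc_table <- screen_lncrnas(bundle, cands, config$auc_cutoff)
  }

  manifest <- list(
    package = "lncSponge",
    version = as.character(utils::packageVersion("lncSponge")),
    parameters = unclass(config),
    seed = config$seed,
    counts = list(
      samples_in = n_samples0, samples_kept = ncol(bundle$mrna),
      genes_in = n_genes0,
      genes_kept = nrow(bundle$mrna) + nrow(bundle$lncrna),
      mirnas = nrow(bundle$mirna),
      power = power,
      modules_found = length(unique(modules$labels[modules$labels > 0])),
      candidates_tested = nrow(sponge$summary),
      sponges_flagged = sum(sponge$summary$is_sponge %||% logical()),
      interactions = nrow(sponge$interactions)
    )
  )

  res <- list(bundle = bundle, power = power, power_fits = fits,
              modules = modules, eigengenes = me,
              trait_correlation = trait_cor, sponge = sponge,
              preservation = preservation, roc = roc_table,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, bundle, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write the standard result tables + manifest under out_dir
write_pipeline_outputs <- function(res, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- res$modules$labels
  utils::write.table(
    data.frame(gene_id = names(labels),
               class = gene_class(bundle, names(labels)),
               module = as.integer(labels)),
    file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_expression_tsv(res$eigengenes$eigengenes,
                       file.path(out_dir, "eigengenes.tsv"))
  utils::write.table(res$trait_correlation,
                     file.path(out_dir, "trait_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$sponge$summary,
                     file.path(out_dir, "sponge_modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$sponge$interactions,
                     file.path(out_dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lncrna_outdegree(res$sponge$interactions),
                     file.path(out_dir, "lncrna_outdegree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$preservation))
    utils::write.table(res$preservation,
                       file.path(out_dir, "preservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$roc))
    utils::write.table(res$roc, file.path(out_dir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth` from [generate_bundle()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(membership = as.list(truth$membership),
         modules = lapply(truth$modules, function(m)
           m[c("id", "lncrna", "mrna", "mirna", "factor_loading",
               "mirna_loading", "is_sponge")]),
         biomarkers = as.list(truth$biomarkers),
         noise_sd = truth$noise_sd, n_samples = truth$n_samples,
         seed = truth$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
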