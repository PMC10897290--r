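# End-to-end pipeline: phantom groups -> measurements -> classifications ->
# widths -> group table -> tests -> report bundle.  Fully reproducible from a
# config plus one seed.

#' Run the full quantification pipeline on phantom groups
#'
#' For each configured group, generates a phantom, measures projection-plane
#' quantities (area, coverage, matrix density), compartment volumes, per-
#' crista classifications and lengths, and per-particle template-bank widths;
#' then assembles the long-format group table, compares every group against
#' the reference with the normality-gated test policy, and (optionally)
#' writes `mito.csv`, `cristae.csv`, `junctions.csv`, `widths.csv`,
#' `tests.csv` and `report.json` to `out_dir`.
#'
#' @param config a named list (or path to a YAML file) with entries
#'   `groups` (named list: each group holds `phantom` arguments for
#'   [phantom_spec()] plus `n_particles`), and optional `reference`
#'   (default the first group), `bank` (arguments for [template_bank()]),
#'   `n_projection_slices` (default 10).
#' @param seed integer master seed; every per-group seed derives from it.
#' @param out_dir optional output directory for the CSV/JSON bundle.
#' @param quiet suppress progress messages (default TRUE).
#' @return a list of class `crista_report`: `mito`, `cristae`, `junctions`,
#'   `widths`, `summary`, `tests` data.frames, the `width_histograms` per
#'   group, and the `config`/`seed` echo.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL, quiet = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$groups) || !length(config$groups))
    stopf("config is missing `groups`")
  gnames <- names(config$groups)
  if (is.null(gnames) || any(gnames == ""))
    stopf("every entry in `groups` must be named")
  reference <- config$reference %||% gnames[1]
  bank_args <- config$bank %||% list()
  bank <- do.call(template_bank, bank_args)
  nproj <- config$n_projection_slices %||% 10L

  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  mito <- list(); cristae <- list(); junctions <- list(); widths <- list()
  hists <- list()

  for (gi in seq_along(config$groups)) {
    gname <- gnames[gi]
    gcfg <- config$groups[[gi]]
    if (is.null(gcfg$phantom))
      stopf("group '%s' is missing its `phantom` entry", gname)
    say("group %s: generating phantom", gname)
    ph_args <- gcfg$phantom
    ph_args$seed <- derive_seed(seed, gi)
    if (!is.null(ph_args$cristae))
      ph_args$cristae <- lapply(ph_args$cristae, function(cs)
        if (inherits(cs, "crista_spec")) cs else do.call(crista_spec, cs))
    spec <- do.call(phantom_spec, ph_args)
    ph <- generate_phantom(spec)

    # projection-plane measurements
    proj <- summed_projection(ph$tomogram, n_slices = nproj)
    norm <- normalize_contrast(proj)
    outline <- ellipse_outline(spec$omm_semi_axes_nm[1:2], spec$center_nm[1:2],
                               spec$voxel_size_nm)
    area <- polygon_area(outline, spec$voxel_size_nm)
    cover <- mito_coverage(area, proj)
    probes <- matrix_probes(spec)
    mdens <- matrix_density(norm, probes)
    vols <- compartment_volumes(ph$labels)
    ncr <- nrow(ph$truth$cristae)
    mito[[gi]] <- data.frame(
      group = gname, mito_id = 1L, area_um2 = area, coverage = cover,
      matrix_density = mdens, n_cristae = ncr,
      cristae_per_um2 = cristae_density(ncr, area),
      matrix_um3 = vols$matrix_um3, ims_um3 = vols$ims_um3,
      cl_um3 = vols$cl_um3, total_um3 = vols$total_um3,
      stringsAsFactors = FALSE)

    # per-crista classification and length
    comps <- crista_components(ph$labels)
    cr_rows <- list()
    class_results <- list()
    for (ci in seq_along(comps)) {
      comp <- comps[[ci]]
      tr <- ph$truth$cristae[ph$truth$cristae$crista_id == comp$crista_id, ]
      jr <- ph$truth$junctions[ph$truth$junctions$crista_id == comp$crista_id, ]
      cl <- classify_shape(comp, n_junctions = tr$n_junctions,
                           lumen_contrast = crista_lumen_contrast(
                             comp, ph$tomogram, ph$labels))
      sk <- skeletonize_crista(comp)
      class_results[[ci]] <- list(shape_class = cl$shape_class,
                                  normal = cl$descriptors$normal,
                                  coords = comp$coords)
      cr_rows[[ci]] <- data.frame(
        group = gname, crista_id = comp$crista_id,
        shape_class = cl$shape_class, unusual_subclass = cl$unusual_subclass,
        directionality = classify_directionality(tr$n_junctions, jr$angle_deg),
        multijunction = classify_multijunction(tr$n_junctions,
                                               cl$descriptors$straightness),
        length_nm = sk$length_nm, true_length_nm = tr$length_nm,
        true_width_nm = tr$width_nm, n_junctions = tr$n_junctions,
        stringsAsFactors = FALSE)
    }
    if (length(cr_rows)) {
      crt <- do.call(rbind, cr_rows)
      crt$stacking <- detect_stacking(class_results)
      cristae[[gi]] <- crt
    }
    if (nrow(ph$truth$junctions)) {
      jt <- ph$truth$junctions
      jt$group <- gname
      junctions[[gi]] <- jt
    }

    # per-particle widths
    n_part <- gcfg$n_particles %||% 0L
    if (n_part > 0L) {
      say("group %s: %d particles", gname, n_part)
      pos <- sample_particles(ph$labels, ph$truth, n_part,
                              seed = derive_seed(seed, 1000L + gi))
      ps <- extract_subtomograms(ph$tomogram, pos, box = bank$box)
      ps <- estimate_widths(ps, bank)
      widths[[gi]] <- width_table(ps, gname)
      hists[[gname]] <- width_histogram(ps$positions$width_nm,
                                        bin_nm = bank$pixel_size_nm)
    }
  }

  mito <- do.call(rbind, mito)
  cristae <- if (length(cristae)) do.call(rbind, cristae) else NULL
  junctions <- if (length(junctions)) do.call(rbind, junctions) else NULL
  widths <- if (length(widths)) do.call(rbind, widths) else NULL

  tbl <- NULL; tests <- NULL; summ <- NULL
  if (!is.null(widths)) {
    tbl <- group_table(widths$group, widths$particle_id, "crista_width_nm",
                       widths$width_nm)
    summ <- summarize_groups(tbl)
    if (length(unique(widths$group)) >= 2L)
      tests <- compare_groups(tbl, reference = reference)
  }

  report <- structure(list(
    mito = mito, cristae = cristae, junctions = junctions, widths = widths,
    summary = summ, tests = tests, width_histograms = hists,
    reference = reference, seed = as.integer(seed)
  ), class = "crista_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## Three horizontal probe lines inside the matrix region of a phantom.
matrix_probes <- function(spec) {
  vox <- spec$voxel_size_nm
  ctr <- spec$center_nm
  a <- spec$omm_semi_axes_nm
  inner <- min(a) - (spec$membrane_thickness_nm * 2 + spec$ibm_gap_nm)
  half <- 0.3 * inner
  offs <- c(-0.25, 0, 0.25) * inner
  lapply(offs, function(o) list(
    p1 = c((ctr[1] - half) / vox + 0.5, (ctr[2] + o) / vox + 0.5),
    p2 = c((ctr[1] + half) / vox + 0.5, (ctr[2] + o) / vox + 0.5)))
}

#' @export
print.crista_report <- function(x, ...) {
  cat("<crista_report>\n")
  cat(sprintf("  groups: %s (reference %s), seed %d\n",
              paste(unique(x$mito$group), collapse = ", "), x$reference, x$seed))
  if (!is.null(x$summary)) {
    cat("  width summary (nm):\n")
    print(x$summary, row.names = FALSE)
  }
  if (!is.null(x$tests)) {
    cat("  tests vs reference:\n")
    print(x$tests[, c("metric", "group_b", "test_name", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' @param report a `crista_report` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "crista_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$mito, "mito.csv")
  wcsv(report$cristae, "cristae.csv")
  wcsv(report$junctions, "junctions.csv")
  wcsv(report$widths, "widths.csv")
  wcsv(report$tests, "tests.csv")
  hist_list <- lapply(report$width_histograms, function(h)
    list(bin_lo = h$bin_lo, bin_hi = h$bin_hi, count = h$count))
  jsonlite::write_json(list(
    seed = report$seed, reference = report$reference,
    summary = report$summary, width_histograms = hist_list
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  invisible(out_dir)
}
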