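#' Run configuration
#'
#' A single nested configuration drives the end-to-end analysis. The
#' `"test"` tier uses coarse meshes suitable for continuous testing; the
#' `"production"` tier is the resolution a real comparative study would
#' run. The whole configuration is serialized alongside any outputs for
#' provenance.
#'
#' @param tier `"test"` or `"production"` mesh resolution preset.
#' @param seed integer seed funnelled to every source of randomness.
#' @param n_species,split clade shape (defaults 15 species, 7 + 8).
#' @param out_dir optional output directory; `NULL` disables file output.
#' @param ... overrides for any nested entry, e.g.
#'   `geometry = list(n_circumferential = 12)`.
#' @return an object of class `run_config` (a nested list).
#' @export
default_config <- function(tier = c("test", "production"), seed = 1,
                           n_species = 15, split = c(7, 8), out_dir = NULL,
                           ...) {
  tier <- match.arg(tier)
  geo <- if (tier == "test") list(n_axial = 12, n_circumferential = 8)
         else list(n_axial = 36, n_circumferential = 24)
  cfg <- list(
    tier = tier, seed = seed, out_dir = out_dir, verbose = TRUE,
    clade = list(n_species = n_species, split = split, seed = seed,
                 trait_params = list()),
    geometry = c(geo, list(tip_fraction = 0.05, zone_center_fraction = 2 / 3,
                           zone_half_width_fraction = 0.025,
                           basal_slice_fraction = 0.02)),
    scale = list(mode = "length", target = 0.05),
    fem = list(tol = 1e-8, resolutions = c(8, 16, 32)),
    materials = list(keratin = list(E = 6.5e9, nu = 0.4, rho = 1000),
                     bone = list(E = 12.7e9, nu = 0.4, rho = 50)),
    loads = list(F = 10, theta = 1.75e-3),
    write_fields = FALSE)
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Entries present in the file override the defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), raw)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks clade shape, mesh resolution floors, loading signs and material
#' admissibility before any compute starts.
#'
#' @param cfg a `run_config`.
#' @return invisibly the config; stops on the first violated constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  cl <- cfg$clade
  if (cl$n_species < 4 || length(cl$split) != 2 || sum(cl$split) != cl$n_species)
    stop("config: invalid clade shape (n_species/split)")
  g <- cfg$geometry
  if (g$n_axial < 4 || g$n_circumferential < 8)
    stop("config: geometry resolution below the minimum (n_axial >= 4, ",
         "n_circumferential >= 8)")
  if (cfg$loads$F <= 0 || cfg$loads$theta <= 0)
    stop("config: loads must be positive")
  for (m in c("keratin", "bone")) {
    mm <- cfg$materials[[m]]
    if (is.null(mm) || mm$E <= 0 || mm$nu < 0 || mm$nu >= 0.5)
      stop("config: invalid material properties for ", m)
  }
  invisible(cfg)
}

cfg_materials <- function(cfg) {
  k <- cfg$materials$keratin
  b <- cfg$materials$bone
  list(keratin = material("keratin", k$E, k$nu, k$rho),
       bone = material("bone", b$E, b$nu, b$rho))
}

#' Run the full comparative excavation analysis
#'
#' The end-to-end pipeline: generate the synthetic clade, mesh every
#' species' bill and scale it to the common length, run the six
#' finite-element solves per species (impact and torsion, each under
#' composite / all-keratin / all-bone material assignments), compute the
#' closed-form beam metrics from the measured base dimensions, and analyse
#' the species table with the correlation/PGLS suite and the
#' composite-vs-homogeneous paired tests. With an output directory set,
#' writes CSV/JSON/VTK artefacts and a plain-text summary.
#'
#' @param config a [default_config()] object.
#' @return an object of class `run_report`: `clade`, `comparative_table`,
#'   `beam`, `stats` (correlation suite), `composite` (paired comparisons
#'   and per-species percentage differences), `timings`, `config`.
#' @export
run_full_analysis <- function(config = default_config()) {
  validate_config(config)
  t_all <- proc.time()[3]
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  timings <- numeric(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- unname(round(proc.time()[3] - t0, 3))
    log_msg("stage %-12s %7.2f s", name, timings[[name]])
    out
  }

  clade <- stage("clade", generate_clade(
    n_species = config$clade$n_species, split = config$clade$split,
    trait_params = config$clade$trait_params, seed = config$clade$seed))

  mats <- cfg_materials(config)
  assignments <- lapply(c(composite = "composite", all_keratin = "all_keratin",
                          all_bone = "all_bone"),
                        function(m) material_assignment(m, mats$keratin, mats$bone))
  cases <- list(impact = load_case("impact", F = config$loads$F),
                torsion = load_case("torsion", theta = config$loads$theta))
  g <- config$geometry

  species <- names(clade$specs)
  peak <- array(NA_real_, c(length(species), 2, 3),
                dimnames = list(species, c("impact", "torsion"),
                                c("composite", "all_keratin", "all_bone")))
  dims <- matrix(NA_real_, length(species), 2,
                 dimnames = list(species, c("width", "depth")))
  meshes <- list()
  fields <- list()

  solves <- stage("fem", {
    n_solved <- 0L
    for (sp in species) {
      mesh <- make_bill_mesh(clade$specs[[sp]], n_axial = g$n_axial,
                             n_circumferential = g$n_circumferential,
                             tip_fraction = g$tip_fraction,
                             zone_center_fraction = g$zone_center_fraction,
                             zone_half_width_fraction = g$zone_half_width_fraction)
      mesh <- scale_mesh(mesh, config$scale$mode, config$scale$target)
      dims[sp, ] <- measure_base_dimensions(mesh, g$basal_slice_fraction)
      for (mode in dimnames(peak)[[3]]) {
        K <- assemble_system(mesh, assignments[[mode]])
        for (rg in c("impact", "torsion")) {
          fld <- if (rg == "impact")
            solve_impact(mesh, assignments[[mode]], cases$impact, K = K,
                         tol = config$fem$tol)
          else
            solve_torsion(mesh, assignments[[mode]], cases$torsion, K = K,
                          tol = config$fem$tol)
          peak[sp, rg, mode] <- peak_vm_in_zone(fld, mesh)
          n_solved <- n_solved + 1L
          if (mode == "composite") fields[[paste(sp, rg, sep = "_")]] <- fld
        }
      }
      meshes[[sp]] <- mesh
    }
    n_solved
  })

  beam <- stage("beam", {
    k <- config$materials$keratin
    out <- do.call(rbind, lapply(species, function(sp)
      beam_metrics(dims[sp, "width"], dims[sp, "depth"],
                   L = config$scale$target, E = k$E, nu = k$nu,
                   theta = config$loads$theta)))
    rownames(out) <- species
    out
  })

  table <- data.frame(
    peak_vm_impact = peak[, "impact", "composite"],
    peak_vm_torsion = peak[, "torsion", "composite"],
    sigma_cr = beam$sigma_cr, tau_max = beam$tau_max,
    width = dims[, "width"], depth = dims[, "depth"],
    body_length = clade$traits[species, "body_length"],
    row.names = species)

  stats_tab <- stage("stats", run_correlation_suite(table, clade$phylogeny))

  composite <- stage("composite", {
    combos <- expand.grid(regime = c("impact", "torsion"),
                          homogeneous = c("all_bone", "all_keratin"),
                          stringsAsFactors = FALSE)
    pct <- list()
    tests <- list()
    for (r in seq_len(nrow(combos))) {
      rg <- combos$regime[r]; hm <- combos$homogeneous[r]
      vm_h <- peak[, rg, hm]
      vm_c <- peak[, rg, "composite"]
      dlab <- paste(rg, sub("all_", "", hm), sep = "_")
      pct[[dlab]] <- 100 * (vm_h - vm_c) / vm_c
      w <- wilcoxon_signed_rank(vm_h, vm_c)
      pt <- phyl_paired_ttest(vm_h, vm_c, clade$phylogeny)
      tests[[dlab]] <- data.frame(
        regime = rg, homogeneous = sub("all_", "", hm),
        median_pct_diff = stats::median(pct[[dlab]]),
        wilcoxon_p = w$p_value, phyl_ttest_p = pt$p_value,
        phyl_ttest_lambda = pt$lambda)
    }
    list(pct_diff = as.data.frame(pct, row.names = species),
         tests = do.call(rbind, tests))
  })

  report <- structure(list(
    clade = clade, comparative_table = table, beam = beam,
    peak_vm = peak, stats = stats_tab, composite = composite,
    n_solves = solves, meshes = meshes, fields = fields,
    timings = c(timings, total = unname(round(proc.time()[3] - t_all, 3))),
    config = config), class = "run_report")

  if (!is.null(config$out_dir)) stage("write", write_report(report, config$out_dir))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d species, %d FE solves (%s tier), %.1f s total\n",
              nrow(x$comparative_table), x$n_solves, x$config$tier,
              x$timings[["total"]]))
  sp <- unique(x$stats[, c("predictor", "response", "spearman_rho", "spearman_p")])
  cat("Spearman correlations:\n")
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-16s vs %-16s rho = %6.3f  p = %.4g\n", sp$predictor[i],
                sp$response[i], sp$spearman_rho[i], sp$spearman_p[i]))
  cat("composite vs homogeneous (median % difference, + favours composite):\n")
  tt <- x$composite$tests
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-7s vs %-7s %+7.2f %%  (Wilcoxon p = %.4g)\n",
                tt$regime[i], tt$homogeneous[i], tt$median_pct_diff[i],
                tt$wilcoxon_p[i]))
  invisible(x)
}

# serialize report artefacts: tables as CSV, stats as JSON, config as YAML,
# composite-regime stress fields as VTK
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  cfg <- report$config
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  utils::write.csv(report$comparative_table, p("comparative_table.csv"))
  utils::write.csv(report$stats, p("pgls_table.csv"), row.names = FALSE)
  utils::write.csv(report$composite$pct_diff, p("composite_pct_diff.csv"))
  utils::write.csv(report$composite$tests, p("composite_tests.csv"),
                   row.names = FALSE)
  ape::write.tree(report$clade$phylogeny, p("phylogeny.nwk"))
  jsonlite::write_json(list(
    seed = cfg$seed, n_species = nrow(report$comparative_table),
    n_solves = report$n_solves,
    spearman = unique(report$stats[, c("predictor", "response",
                                       "spearman_rho", "spearman_p")]),
    composite_tests = report$composite$tests,
    timings = as.list(report$timings)),
    p("stats.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (isTRUE(cfg$write_fields)) {
    dir.create(p("fields"), showWarnings = FALSE)
    for (nm in names(report$fields)) {
      sp <- sub("_(impact|torsion)$", "", nm)
      write_vtk(report$meshes[[sp]], p("fields", paste0(nm, ".vtk")),
                point_data = list(von_mises = report$fields[[nm]]$nodal_vm),
                title = nm)
    }
  }
  con <- file(p("summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(out_dir)
}

#' Export figure-style tables from a run report
#'
#' Writes the per-species peak-stress table (heat-map companion), the
#' species performance scatter (width, depth, both peak stresses), the
#' theoretical performance-space grids spanning the observed morphospace,
#' and the composite-vs-homogeneous paired-difference table.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @param n_grid grid resolution per axis for the performance space.
#' @return invisibly the paths written.
#' @export
make_fig_tables <- function(report, out_dir, n_grid = 25) {
  if (!inherits(report, "run_report") || nrow(report$comparative_table) == 0)
    stop("empty or invalid run report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$comparative_table
  p <- function(...) file.path(out_dir, ...)

  peak_long <- do.call(rbind, lapply(dimnames(report$peak_vm)[[2]], function(rg)
    do.call(rbind, lapply(dimnames(report$peak_vm)[[3]], function(md)
      data.frame(species = rownames(tab), regime = rg, materials = md,
                 peak_vm = report$peak_vm[, rg, md])))))
  utils::write.csv(peak_long, p("species_peak_vm.csv"), row.names = FALSE)

  scatter <- tab[, c("width", "depth", "peak_vm_impact", "peak_vm_torsion")]
  scatter <- cbind(species = rownames(tab), scatter)
  utils::write.csv(scatter, p("species_scatter.csv"), row.names = FALSE)

  k <- report$config$materials$keratin
  grid <- performance_grid(range(tab$width), range(tab$depth), E = k$E,
                           nu = k$nu, theta = report$config$loads$theta,
                           L = report$config$scale$target, n_grid = n_grid)
  utils::write.csv(grid, p("performance_grid.csv"), row.names = FALSE)

  utils::write.csv(report$composite$pct_diff, p("paired_differences.csv"))
  invisible(c(p("species_peak_vm.csv"), p("species_scatter.csv"),
              p("performance_grid.csv"), p("paired_differences.csv")))
}
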