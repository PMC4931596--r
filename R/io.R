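# Configuration, persistence and run manifests. Formats: YAML config,
# extended-XYZ snapshots, CSV fields, JSON defects/labels/manifests.
# One precision (float64 / %.17g) everywhere.

known_config_keys <- c("L_over_D", "eta", "R_outer", "R_inner", "H",
                       "n_sweeps", "sample_every", "delta_t", "delta_r",
                       "seed", "mode", "cell_size", "seg_len", "s_floor",
                       "threshold", "merge_radius", "charge_radius",
                       "w_b", "c_inf", "rho", "offset",
                       "a2", "a4", "K", "grid_spacing", "step", "tol",
                       "max_iter", "noise")

#' Load and validate a run configuration
#'
#' Reads a YAML file, applies defaults, validates every invariant
#' (plate spacing below the rod length, rod-accessible gap, packing
#' fraction in range) and rejects unknown keys so typos fail loudly.
#'
#' @param path YAML file with at least `L_over_D`, `eta`, `R_outer`,
#'   `R_inner`, `H`.
#' @return List with `params` ([sim_params()]), `confinement`,
#'   `analysis`, `classify` and `continuum` parameter sets, plus the
#'   effective key-value list in `effective`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown) > 0)
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  need <- c("L_over_D", "eta", "R_outer", "R_inner", "H")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    abort(paste("missing required config key(s):",
                paste(missing, collapse = ", ")))
  if (cfg$H >= cfg$L_over_D)
    abort("invalid config: plate spacing H must be smaller than the rod length L")
  conf <- confinement(cfg$R_outer, cfg$R_inner, cfg$H)
  params <- sim_params(
    L_over_D = cfg$L_over_D, eta = cfg$eta,
    n_sweeps = cfg$n_sweeps %||% 1000,
    sample_every = cfg$sample_every %||% 10,
    delta_t = cfg$delta_t, delta_r = cfg$delta_r,
    seed = cfg$seed %||% 1, mode = cfg$mode %||% "auto")
  analysis <- list(cell_size = cfg$cell_size %||% 1,
                   seg_len = cfg$seg_len %||% 0.5,
                   s_floor = cfg$s_floor %||% 0.05,
                   threshold = cfg$threshold %||% 0.5,
                   merge_radius = cfg$merge_radius %||% 2,
                   charge_radius = cfg$charge_radius %||% 3)
  classify <- list(w_b = cfg$w_b %||% (cfg$L_over_D / 2),
                   c_inf = cfg$c_inf %||% 5,
                   rho = cfg$rho %||% 2,
                   offset = cfg$offset %||% 0.5)
  continuum <- continuum_params(
    a2 = cfg$a2 %||% -1, a4 = cfg$a4 %||% 1, K = cfg$K %||% 1,
    grid_spacing = cfg$grid_spacing %||% 0.4, step = cfg$step,
    tol = cfg$tol %||% 1e-8, max_iter = cfg$max_iter %||% 300000,
    noise = cfg$noise %||% 0.01, seed = cfg$seed %||% 1)
  effective <- c(cfg, list())
  list(params = params, confinement = conf, analysis = analysis,
       classify = classify, continuum = continuum, effective = effective)
}

#' Write a rod configuration as extended XYZ
#'
#' One frame: count line, a comment line carrying L, D and the chamber
#' geometry, then one `C x y z ux uy uz` row per rod at full float64
#' precision.
#'
#' @param config A [rod_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rods_xyz <- function(config, path) {
  conf <- attr(config, "confinement")
  hdr <- sprintf(
    'L=%.17g D=1 R_outer=%.17g R_inner=%.17g H=%.17g nonphysical=%d',
    attr(config, "L"), conf$R_outer, conf$R_inner, conf$H,
    as.integer(attr(config, "nonphysical")))
  rows <- sprintf("C %.17g %.17g %.17g %.17g %.17g %.17g",
                  config$x, config$y, config$z,
                  config$ux, config$uy, config$uz)
  writeLines(c(as.character(nrow(config)), hdr, rows), path)
  invisible(path)
}

#' Read an extended-XYZ rod configuration
#'
#' @param path File written by [write_rods_xyz()].
#' @return A [rod_config()].
#' @export
read_rods_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  kv <- strsplit(strsplit(lines[2], "\\s+")[[1]], "=")
  meta <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  conf <- confinement(meta[["R_outer"]], meta[["R_inner"]], meta[["H"]])
  if (n == 0) {
    return(rod_config(tibble(x = numeric(), y = numeric(), z = numeric(),
                             ux = numeric(), uy = numeric(), uz = numeric()),
                      meta[["L"]], conf,
                      nonphysical = meta[["nonphysical"]] > 0))
  }
  m <- do.call(rbind, lapply(lines[3:(2 + n)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][-1])))
  rod_config(tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                    ux = m[, 4], uy = m[, 5], uz = m[, 6]),
             meta[["L"]], conf, nonphysical = meta[["nonphysical"]] > 0)
}

#' Write a field tibble as CSV with grid metadata
#'
#' @param field Any field tibble carrying a `grid2d` attribute.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  g <- field_grid(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# grid nx=%d ny=%d cell_size=%.17g x0=%.17g R_outer=%.17g R_inner=%.17g H=%.17g",
    g$nx, g$ny, g$cell_size, g$x0, g$conf$R_outer, g$conf$R_inner, g$conf$H),
    con)
  utils::write.csv(as.data.frame(field), con, row.names = FALSE)
  invisible(path)
}

#' Read a field CSV written by [write_field_csv()]
#'
#' @param path File path.
#' @return A field tibble with its `grid2d` attribute restored.
#' @export
read_field_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(strsplit(sub("^# grid ", "", hdr), "\\s+")[[1]], "=")
  meta <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  df <- as_tibble(utils::read.csv(path, skip = 1))
  conf <- confinement(meta[["R_outer"]], meta[["R_inner"]], meta[["H"]])
  nx <- as.integer(meta[["nx"]])
  xs <- meta[["x0"]] + (seq_len(nx) - 0.5) * meta[["cell_size"]]
  cls <- if ("theta" %in% names(df)) "director_field" else "qfield"
  grid <- structure(list(nx = nx, ny = as.integer(meta[["ny"]]),
                         cell_size = meta[["cell_size"]], x0 = meta[["x0"]],
                         y0 = meta[["x0"]], xs = xs, ys = xs,
                         mask = if ("mask" %in% names(df)) df$mask else rep(TRUE, nrow(df)),
                         conf = conf), class = "grid2d")
  structure(df, grid = grid, class = c(cls, class(tibble())))
}

#' Write / read defect records as JSON
#'
#' @param defects Defect tibble from [detect_defects()].
#' @param path File path.
#' @return `path` (write) or the defect tibble (read).
#' @export
write_defects_json <- function(defects, path) {
  jsonlite::write_json(as.data.frame(defects), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_defects_json
#' @export
read_defects_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run manifest
#'
#' Records package version, seed and a hash of the effective
#' configuration, so that seed + config hash fully determine stochastic
#' outputs.
#'
#' @param seed Integer seed used for the run.
#' @param config Effective configuration list.
#' @param extra Optional named list of run summaries (acceptance rate,
#'   final order parameter, ...).
#' @return A manifest list.
#' @export
run_manifest <- function(seed, config, extra = list()) {
  c(list(package = "confinedrods",
         version = as.character(utils::packageVersion("confinedrods")),
         seed = seed,
         config_hash = rlang::hash(config)),
    extra)
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path Output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
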