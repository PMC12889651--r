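#' Generate a synthetic ligand library
#'
#' Each ligand is reduced to the one latent quantity that controls pose
#' stability in the toy model: the depth of its binding well (kT). Binders
#' draw their depth from a deeper distribution than non-binders; both are
#' truncated-at-zero normals (negative draws are redrawn). Defaults emulate
#' a realistic screen composition of 5 binders against 27 non-binders
#' (a ~16% hit rate) with a clear but noisy stability separation of
#' 8 vs 2 kT.
#'
#' @param n_binders,n_nonbinders library composition (>= 0; defaults 5
#'   and 27).
#' @param depth_binder_mean,depth_nonbinder_mean mean well depths in kT
#'   (defaults 8 and 2).
#' @param depth_sd common depth standard deviation (default 1).
#' @param seed RNG seed; the library and the per-ligand `seed_base` values
#'   are deterministic given it.
#' @return data.frame of class `ligand_library`: columns `ligand_id`,
#'   `true_label`, `well_depth`, `seed_base`. Replica seeds are derived as
#'   `seed_base + replica_index`.
#' @export
gen_library <- function(n_binders = 5L, n_nonbinders = 27L,
                        depth_binder_mean = 8, depth_nonbinder_mean = 2,
                        depth_sd = 1, seed = 1L) {
  if (n_binders < 0 || n_nonbinders < 0) stop("counts must be non-negative")
  stopifnot(depth_binder_mean >= 0, depth_nonbinder_mean >= 0, depth_sd >= 0)
  n <- n_binders + n_nonbinders
  set.seed(as.integer(seed))
  rtrunc0 <- function(n, mean, sd) {
    if (n == 0L) return(numeric())
    if (sd == 0) return(rep(mean, n))
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  depths <- c(rtrunc0(n_binders, depth_binder_mean, depth_sd),
              rtrunc0(n_nonbinders, depth_nonbinder_mean, depth_sd))
  # replica seeds are seed_base + replica index; keep well inside 32-bit range
  base0 <- (abs(as.integer(seed)) %% 1000000L) * 1000L
  structure(
    data.frame(
      ligand_id = sprintf("lig%03d", seq_len(n)),
      true_label = rep(c("binder", "nonbinder"), c(n_binders, n_nonbinders)),
      well_depth = depths,
      seed_base = base0 + 100L * seq_len(n),
      stringsAsFactors = FALSE
    ),
    class = c("ligand_library", "data.frame")
  )
}

#' Run the CTMD pipeline over a synthetic library
#'
#' For every ligand, runs `n_replicas` independent well-tempered
#' metadynamics trajectories on a Gaussian-well potential of that ligand's
#' latent depth, evaluates the terminal c(t) of each replica, and takes the
#' minimum as the CTMD score. Optionally writes one PLUMED-style HILLS file
#' per replica under `out_dir/<ligand_id>/rep<i>/HILLS`. Fully
#' deterministic: replica seeds are `seed_base + replica_index`.
#'
#' @param library a [gen_library()] data.frame.
#' @param dyn a [dyn_params()] template (its `seed` field is overridden per
#'   replica).
#' @param metad a [metad_params()].
#' @param n_replicas independent replicas per ligand (default 3, the CTMD
#'   protocol's "a few short runs").
#' @param thermo a [thermo_params()].
#' @param grid a [ct_grid()]; default: the potential's accessible range.
#' @param width,wall_position,wall_stiffness shared landscape geometry of
#'   the per-ligand Gaussian wells.
#' @param out_dir if non-NULL, directory to receive the HILLS tree
#'   (created; must be writable).
#' @return a [screen_table()] with extra columns `well_depth` and
#'   `ligand_score` details dropped; one row per ligand, `label` taken from
#'   `true_label`.
#' @export
simulate_screen <- function(library, dyn = dyn_params(),
                            metad = metad_params(), n_replicas = 3L,
                            thermo = thermo_params(), grid = NULL,
                            width = 0.1, wall_position = 1,
                            wall_stiffness = 100, out_dir = NULL) {
  if (!is.data.frame(library) || nrow(library) == 0L) {
    stop("`library` must be a non-empty ligand library")
  }
  stopifnot(all(c("ligand_id", "true_label", "well_depth", "seed_base") %in%
                  names(library)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
      stop(sprintf("output directory not writable: %s", out_dir))
    }
  }
  if (is.null(grid)) {
    proto <- potential_spec("gaussian_well", depth = 0, width = width,
                            wall_position = wall_position,
                            wall_stiffness = wall_stiffness)
    grid <- default_grid(proto, sigma_max = metad$sigma)
  }
  scores <- numeric(nrow(library))
  for (i in seq_len(nrow(library))) {
    spec <- potential_spec("gaussian_well", depth = library$well_depth[i],
                           width = width, center = 0,
                           wall_position = wall_position,
                           wall_stiffness = wall_stiffness)
    terminals <- numeric(n_replicas)
    for (r in seq_len(n_replicas)) {
      dyn_r <- dyn_params(dt = dyn$dt, friction = dyn$friction, kT = dyn$kT,
                          n_steps = dyn$n_steps,
                          seed = library$seed_base[i] + r)
      hl <- run_wtmetad(spec, dyn_r, metad, thermo)
      if (!is.null(out_dir)) {
        rep_dir <- file.path(out_dir, library$ligand_id[i], sprintf("rep%d", r))
        dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
        write_hills(hl, file.path(rep_dir, "HILLS"), thermo)
      }
      # hills pile against the reflecting s = 0 edge by construction; the
      # quadrature domain starts there intentionally, so no edge warning
      terminals[r] <- if (nrow(hl) == 0L) 0 else
        ct_value(hl, Inf, grid, thermo, warn_edges = FALSE)
    }
    scores[i] <- min(terminals)
  }
  out <- screen_table(library$ligand_id, scores, library$true_label)
  out$well_depth <- library$well_depth
  if (!is.null(out_dir)) {
    write.table(out, file.path(out_dir, "screen.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  out
}

#' Quick hill-list fixtures without running dynamics
#'
#' Two caricatures of a metadynamics run for fast unit tests: a `"stuck"`
#' pose whose hill centers jitter narrowly around one point (bias piles up,
#' high terminal c(t)) and an `"escaping"` pose whose centers drift across
#' the whole grid (bias spreads thinly, lower terminal c(t)). Heights
#' follow the well-tempered rule evaluated on the hills deposited so far.
#'
#' @param profile `"stuck"` or `"escaping"`.
#' @param n_hills number of hills (>= 0), default 200.
#' @param seed RNG seed.
#' @param w0 initial hill height, kT (default 0.5).
#' @param sigma hill width (default 0.02).
#' @param thermo a [thermo_params()].
#' @param s_range CV range across which escaping centers drift, default
#'   `c(0, 1)`.
#' @return a [hills()] object.
#' @export
fast_hills_fixture <- function(profile = c("stuck", "escaping"),
                               n_hills = 200L, seed = 1L,
                               w0 = 0.5, sigma = 0.02,
                               thermo = thermo_params(),
                               s_range = c(0, 1)) {
  profile <- match.arg(profile)
  stopifnot(n_hills >= 0)
  thermo <- as_thermo(thermo)
  if (n_hills == 0L) return(hills())
  set.seed(as.integer(seed))
  anchor <- mean(s_range)
  centers <- if (profile == "stuck") {
    pmax(anchor + 0.02 * rnorm(n_hills), 0)
  } else {
    drift <- seq(s_range[1], s_range[2], length.out = n_hills)
    pmax(drift + 0.02 * rnorm(n_hills), 0)
  }
  times <- seq_len(n_hills)
  # well-tempered heights against the running bias, vectorised incrementally
  heights <- numeric(n_hills)
  for (k in seq_len(n_hills)) {
    v <- if (k == 1L) 0 else {
      sum(heights[1:(k - 1L)] *
            exp(-(centers[k] - centers[1:(k - 1L)])^2 / (2 * sigma^2)))
    }
    heights[k] <- wt_hill_height(w0, v, thermo)
  }
  hills(time = times, center = centers, sigma = sigma, height = heights)
}
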