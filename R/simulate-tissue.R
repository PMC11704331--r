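#' Configuration for the virtual tissue generator
#'
#' Parameters of a two-class Thomas cluster process with an immune population
#' attracted to one of the classes. Two transcription-factor (TF) marker
#' classes (`TF_A`, `TF_B`) are laid down as clustered point patterns whose
#' cluster centers ("parents") repel each other across classes; immune cells
#' follow an inhomogeneous Poisson process whose intensity decays with
#' distance to the nearest parent of the attracted class. This emulates the
#' spatial structure of whole-slide cell detections in which two mutually
#' exclusive TF-high tumor regions coexist and myeloid cells accumulate
#' around one of them.
#'
#' @param window_width,window_height Window size in micrometers.
#' @param parent_intensity_per_class Expected cluster parents per um^2, per
#'   TF class.
#' @param offspring_mean Expected cells per parent (Poisson).
#' @param offspring_sd Isotropic Gaussian displacement sigma of offspring
#'   around their parent, in um.
#' @param class_exclusion_radius Minimum distance delta (um) between parents
#'   of different TF classes, enforced by rejection sampling.
#' @param immune_baseline_intensity Baseline immune intensity (cells/um^2).
#' @param immune_attraction_amplitude Added immune intensity (cells/um^2) at
#'   distance zero from an attracted-class parent.
#' @param immune_attraction_scale Exponential decay length rho (um) of the
#'   attraction term.
#' @param attracted_class TF class label the immune cells are attracted to.
#' @param seed Integer seed; fixes the output exactly.
#'
#' @return A list of class `tissue_sim_config`.
#' @seealso [simulate_tissue()]
#' @export
tissue_sim_config <- function(window_width = 2000,
                              window_height = 2000,
                              parent_intensity_per_class = 5e-6,
                              offspring_mean = 50,
                              offspring_sd = 40,
                              class_exclusion_radius = 300,
                              immune_baseline_intensity = 1e-5,
                              immune_attraction_amplitude = 1e-4,
                              immune_attraction_scale = 100,
                              attracted_class = "TF_A",
                              seed = 1L) {
  check_scalar(window_width, "window_width", positive = TRUE)
  check_scalar(window_height, "window_height", positive = TRUE)
  check_scalar(parent_intensity_per_class, "parent_intensity_per_class", nonneg = TRUE)
  check_scalar(offspring_mean, "offspring_mean", nonneg = TRUE)
  check_scalar(offspring_sd, "offspring_sd", positive = TRUE)
  check_scalar(class_exclusion_radius, "class_exclusion_radius", nonneg = TRUE)
  check_scalar(immune_baseline_intensity, "immune_baseline_intensity", nonneg = TRUE)
  check_scalar(immune_attraction_amplitude, "immune_attraction_amplitude", nonneg = TRUE)
  check_scalar(immune_attraction_scale, "immune_attraction_scale", positive = TRUE)
  if (!attracted_class %in% c("TF_A", "TF_B")) {
    stop_spatsig("'attracted_class' must be \"TF_A\" or \"TF_B\"")
  }
  structure(
    list(
      window_width = window_width, window_height = window_height,
      parent_intensity_per_class = parent_intensity_per_class,
      offspring_mean = offspring_mean, offspring_sd = offspring_sd,
      class_exclusion_radius = class_exclusion_radius,
      immune_baseline_intensity = immune_baseline_intensity,
      immune_attraction_amplitude = immune_attraction_amplitude,
      immune_attraction_scale = immune_attraction_scale,
      attracted_class = attracted_class,
      seed = seed
    ),
    class = "tissue_sim_config"
  )
}

#' Simulate a marked point pattern of tumor and immune cells
#'
#' Generates a cell-detection table with the structure produced by
#' whole-slide image analysis: cell centroids in micrometers (origin
#' top-left, y increasing downward) carrying one marker class each. TF cells
#' follow a Thomas cluster process per class (parents Poisson in the window,
#' offspring counts Poisson, isotropic Gaussian displacement; offspring
#' falling outside the window are discarded). Parents of the two TF classes
#' are kept at least `class_exclusion_radius` apart by rejection sampling
#' with a retry cap; exhausting the cap is an explicit error, never a silent
#' relaxation. Immune cells are drawn by thinning a homogeneous Poisson
#' proposal at rate `base + amplitude`, accepting each point with probability
#' `(base + amplitude * exp(-d/rho)) / (base + amplitude)` where `d` is its
#' distance to the nearest attracted-class parent.
#'
#' @param config A [tissue_sim_config()].
#' @param max_parent_attempts Rejection-sampling cap per cross-class parent.
#'
#' @return A list with `cells` (data.frame: `cell_id`, `x_um`, `y_um`,
#'   `class`) and `parents` (ground-truth data.frame: `parent_id`, `x_um`,
#'   `y_um`, `class`).
#' @export
simulate_tissue <- function(config, max_parent_attempts = 1000L) {
  stopifnot(inherits(config, "tissue_sim_config"))
  with_seed(config$seed, {
    W <- config$window_width
    H <- config$window_height
    area <- W * H

    n_a <- stats::rpois(1L, config$parent_intensity_per_class * area)
    pa <- cbind(stats::runif(n_a, 0, W), stats::runif(n_a, 0, H))

    # cross-class exclusion: TF_B parents rejected within delta of a TF_A parent
    n_b <- stats::rpois(1L, config$parent_intensity_per_class * area)
    delta <- config$class_exclusion_radius
    pb <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(n_b)) {
      placed <- FALSE
      for (attempt in seq_len(max_parent_attempts)) {
        cand <- c(stats::runif(1L, 0, W), stats::runif(1L, 0, H))
        ok <- n_a == 0L ||
          min(sqrt((pa[, 1L] - cand[1L])^2 + (pa[, 2L] - cand[2L])^2)) >= delta
        if (ok) {
          pb <- rbind(pb, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_spatsig(
          "window too small to satisfy class_exclusion_radius = ", delta,
          " um after ", max_parent_attempts, " rejection attempts"
        )
      }
    }

    offspring <- function(parents, label) {
      if (nrow(parents) == 0L || config$offspring_mean == 0) {
        return(cbind(x = numeric(0), y = numeric(0)))
      }
      counts <- stats::rpois(nrow(parents), config$offspring_mean)
      idx <- rep.int(seq_len(nrow(parents)), counts)
      n <- length(idx)
      x <- parents[idx, 1L] + stats::rnorm(n, 0, config$offspring_sd)
      y <- parents[idx, 2L] + stats::rnorm(n, 0, config$offspring_sd)
      keep <- x >= 0 & x <= W & y >= 0 & y <= H
      cbind(x = x[keep], y = y[keep])
    }
    off_a <- offspring(pa, "TF_A")
    off_b <- offspring(pb, "TF_B")

    # immune placement: thinning of a homogeneous proposal (exact for an
    # intensity bounded by base + amplitude)
    base <- config$immune_baseline_intensity
    amp <- config$immune_attraction_amplitude
    rho <- config$immune_attraction_scale
    attracted <- if (config$attracted_class == "TF_A") pa else pb
    m <- stats::rpois(1L, (base + amp) * area)
    ix <- stats::runif(m, 0, W)
    iy <- stats::runif(m, 0, H)
    if (m > 0L) {
      if (nrow(attracted) > 0L && amp > 0) {
        d <- nearest_point_distance(ix, iy, attracted)
        lambda <- base + amp * exp(-d / rho)
      } else {
        lambda <- rep.int(base, m)
      }
      accept <- stats::runif(m) < lambda / (base + amp)
      ix <- ix[accept]
      iy <- iy[accept]
    }

    x <- c(off_a[, 1L], off_b[, 1L], ix)
    y <- c(off_a[, 2L], off_b[, 2L], iy)
    cls <- c(
      rep.int("TF_A", nrow(off_a)), rep.int("TF_B", nrow(off_b)),
      rep.int("IMMUNE_1", length(ix))
    )
    cells <- data.frame(
      cell_id = sprintf("cell_%06d", seq_along(x)),
      x_um = x, y_um = y, class = cls,
      stringsAsFactors = FALSE
    )
    parents <- data.frame(
      parent_id = sprintf("parent_%04d", seq_len(n_a + nrow(pb))),
      x_um = c(pa[, 1L], pb[, 1L]),
      y_um = c(pa[, 2L], pb[, 2L]),
      class = c(rep.int("TF_A", n_a), rep.int("TF_B", nrow(pb))),
      stringsAsFactors = FALSE
    )
    list(cells = cells, parents = parents)
  })
}

# Distance from each (x, y) to the nearest row of `pts` (2-column matrix).
nearest_point_distance <- function(x, y, pts) {
  vapply(seq_along(x), function(i) {
    min(sqrt((pts[, 1L] - x[i])^2 + (pts[, 2L] - y[i])^2))
  }, numeric(1L))
}
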