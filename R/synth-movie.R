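#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their parameters and `seed`, without touching global RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic aggregation movie
#'
#' Cells are dark disks on a bright background (transmitted-light polarity)
#' that drift radially toward the well centroid; the contraction factor of
#' each frame is solved numerically (bisection on the rendered footprint) so
#' that the total rendered footprint tracks the kinetics model's normalized
#' area. Merging of aggregates is implicit through disk overlap. Seeding
#' emulates the post-centrifugation state of the aggregation assay: cell
#' centres are drawn uniformly in a central disk of radius
#' `seed_radius_frac * min(image_shape)`, overlapping freely (a pellet is
#' several cells deep). Cells carry
#' fixed z positions spread uniformly over the acquisition depth span; in
#' each focal plane a cell is blurred with a Gaussian whose sigma grows
#' linearly with its distance from the plane, and i.i.d. Gaussian read noise
#' is added.
#'
#' The per-frame ground-truth mask and footprint area are returned
#' alongside. The truth mask is the union of the sharp cell disks with
#' holes smaller than one cell cross-section filled: interstitial speckle
#' below the cell scale is an artifact of projecting a multi-layer pellet
#' onto 2-D disks, whereas a real pellet has no sub-cellular background
#' gaps. Larger (resolvable) cell-free holes remain holes.
#'
#' @param model a [kinetics_model()].
#' @param geometry an [acquisition_geometry()].
#' @param n_cells number of seeded cells.
#' @param cell_radius_px cell radius in pixels.
#' @param seed RNG seed; identical seed and parameters give an identical
#'   movie.
#' @param background background intensity (arbitrary units in `[0, 1]`).
#' @param contrast darkness amplitude of a cell relative to background.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param blur_focus in-focus blur sigma (px).
#' @param blur_per_um additional blur sigma per um of defocus. The default
#'   is the second-moment-equivalent Gaussian sigma of the geometric defocus
#'   disk of an NA 0.3 objective at 0.645 um/px (half the disk radius);
#'   the rendered sigma is capped at `blur_cap` px for tractability.
#' @param blur_cap maximum rendered blur sigma (px).
#' @param seed_radius_frac seeding-disk radius as a fraction of the shorter
#'   image side.
#' @param jitter_px per-frame random-walk jitter sd of cell centres (px).
#' @param area_tol relative tolerance of the footprint-vs-target solve.
#' @param frame_callback optional `function(stack, frame_index)`; when given,
#'   rendered planes are passed to the callback and not retained (streaming
#'   mode for large movies), and `frames` in the result is `NULL`.
#' @return An `agg_movie`: list with `frames` (per frame, list of plane
#'   matrices), `truth` (`footprint_px`, `masks`), `target` (the sampled
#'   kinetics curve), `geometry`, `model` and the generation parameters.
#' @export
render_movie <- function(model, geometry = acquisition_geometry(),
                         n_cells = 500, cell_radius_px = 11, seed = 1,
                         background = 0.85, contrast = 0.45,
                         noise_sd = 0.02, blur_focus = 0.6,
                         blur_per_um = 0.23, blur_cap = 15,
                         seed_radius_frac = 0.35, jitter_px = 0.5,
                         area_tol = 0.01, frame_callback = NULL) {
  stopifnot(inherits(model, "kinetics_model"),
            inherits(geometry, "acquisition_geometry"))
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  H <- geometry$image_shape[1]; W <- geometry$image_shape[2]
  r_well <- seed_radius_frac * min(H, W)
  # a pellet more than ~3 cell layers deep cannot be rendered meaningfully
  if (3 * pi * r_well^2 < n_cells * pi * cell_radius_px^2)
    stop("image too small to hold ", n_cells,
         " cells without full overlap at t = 0")
  target <- simulate_kinetics(model, geometry)
  n_frames <- nrow(target)
  min_hole <- pi * cell_radius_px^2
  pellet_mask <- function(pr, pc) {
    m <- cpp_render_disks(pr, pc, cell_radius_px, H, W)
    filled <- cpp_fill_holes(m)
    holes <- filled & !m
    if (any(holes)) {
      lab <- cpp_label8(holes)
      n_h <- max(lab)
      if (n_h > 0) {
        sizes <- tabulate(lab[lab > 0], nbins = n_h)
        big <- which(sizes >= min_hole)
        if (length(big)) filled[lab %in% big] <- FALSE
      }
    }
    filled
  }
  with_seed(seed, {
    # uniform positions in the well disk
    rr <- r_well * sqrt(runif(n_cells))
    th <- runif(n_cells, 0, 2 * pi)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    q_r <- rr * sin(th); q_c <- rr * cos(th)      # offsets from centre
    z <- runif(n_cells, 0, geometry$depth_span)
    plane_z <- seq(0, geometry$depth_span, by = geometry$plane_spacing)
    zbin <- pmax(1L, pmin(length(plane_z),
                          1L + as.integer(round(z / geometry$plane_spacing))))
    f0 <- sum(pellet_mask(cy + q_r, cx + q_c))
    footprint <- numeric(n_frames)
    masks <- vector("list", n_frames)
    frames <- if (is.null(frame_callback)) vector("list", n_frames) else NULL
    for (f in seq_len(n_frames)) {
      if (f > 1L) {
        q_r <- q_r + rnorm(n_cells, 0, jitter_px)
        q_c <- q_c + rnorm(n_cells, 0, jitter_px)
      }
      goal <- target$normalized_area[f] * f0
      eval_fp <- function(s) sum(pellet_mask(cy + s * q_r, cx + s * q_c))
      s <- 1
      if (eval_fp(1) > goal * (1 + area_tol)) {
        lo <- 1e-3; hi <- 1
        for (it in 1:40) {
          s <- (lo + hi) / 2
          fp <- eval_fp(s)
          if (abs(fp - goal) <= area_tol * goal) break
          if (fp > goal) hi <- s else lo <- s
        }
      }
      pr <- cy + s * q_r; pc <- cx + s * q_c
      gt <- pellet_mask(pr, pc)
      footprint[f] <- sum(gt)
      masks[[f]] <- gt
      # per-plane rendering: blur each z-bin's sharp footprint by defocus
      planes <- vector("list", geometry$n_planes)
      bin_masks <- lapply(seq_along(plane_z), function(b) {
        sel <- zbin == b
        if (!any(sel)) return(NULL)
        m <- cpp_render_disks(pr[sel], pc[sel], cell_radius_px, H, W)
        storage.mode(m) <- "double"
        m
      })
      for (p in seq_len(geometry$n_planes)) {
        dark <- matrix(0, H, W)
        for (b in seq_along(plane_z)) {
          if (is.null(bin_masks[[b]])) next
          sig <- min(blur_cap,
                     blur_focus + blur_per_um * abs(plane_z[b] - plane_z[p]))
          dark <- dark + cpp_gauss_blur(bin_masks[[b]], sig)
        }
        img <- background - contrast * pmin(dark, 1.4) +
          matrix(rnorm(H * W, 0, noise_sd), H, W)
        img[img < 0] <- 0; img[img > 1] <- 1
        planes[[p]] <- img
      }
      stack <- image_stack(planes, pixel_size = geometry$pixel_size,
                           time_index = f - 1L)
      if (is.null(frame_callback)) frames[[f]] <- stack
      else frame_callback(stack, f)
    }
    structure(list(frames = frames,
                   truth = list(footprint_px = footprint, masks = masks),
                   target = target, geometry = geometry, model = model,
                   params = list(n_cells = n_cells,
                                 cell_radius_px = cell_radius_px, seed = seed,
                                 background = background, contrast = contrast,
                                 noise_sd = noise_sd, blur_focus = blur_focus,
                                 blur_per_um = blur_per_um, blur_cap = blur_cap,
                                 seed_radius_frac = seed_radius_frac,
                                 jitter_px = jitter_px, area_tol = area_tol)),
              class = "agg_movie")
  })
}

#' Extract the list of image stacks from a rendered movie
#' @param movie an `agg_movie` from [render_movie()].
#' @return List of [image_stack] objects.
#' @export
movie_stacks <- function(movie) {
  stopifnot(inherits(movie, "agg_movie"))
  if (is.null(movie$frames))
    stop("movie was rendered in streaming mode; frames were not retained")
  movie$frames
}

#' @export
print.agg_movie <- function(x, ...) {
  cat(sprintf(
    "agg_movie: %d frame(s), %d plane(s)/frame, %dx%d px, %d cells, seed %s\n",
    nrow(x$target), x$geometry$n_planes, x$geometry$image_shape[1],
    x$geometry$image_shape[2], x$params$n_cells, format(x$params$seed)))
  invisible(x)
}
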