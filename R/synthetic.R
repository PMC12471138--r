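#' Specification of a synthetic fundus cohort
#'
#' A `cohort_spec` states everything the generator needs to produce one
#' labelled group of synthetic fundus images with ground-truth vessel masks:
#' the vessel-tree geometry (density, roots, branching, width, tortuosity),
#' the chromatic model of the background (RGB means/SDs and the
#' pathology-modelling green/blue shifts), the noise level, and the master
#' seed. Identical specs (including seed) produce bit-identical cohorts.
#'
#' @param group_name group label attached to every generated image.
#' @param n_images number of images in the cohort (>= 1).
#' @param image_size integer `c(height, width)` in pixels (>= 64 each).
#' @param vessel_density target vessel-pixel fraction inside the circular
#'   field, in `[0, 0.5)` (0 yields empty masks).
#' @param root_count number of vessel roots seeded on the optic disc.
#' @param branch_prob per-step probability that a walker spawns a child
#'   branch.
#' @param width_mean,width_sd root vessel width in pixels (mean >= 1).
#' @param tortuosity per-step heading jitter SD in radians.
#' @param background_rgb_mean,background_rgb_sd length-3 vectors of 8-bit
#'   background channel means and SDs.
#' @param green_shift,blue_shift signed additive chromatic offsets (8-bit
#'   units) applied to the green/blue background means; the knob that models
#'   pathology-related chromatic change.
#' @param noise_sd additive pixel noise SD (8-bit units).
#' @param seed master RNG seed of the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_name = "healthy", n_images = 15,
                        image_size = c(256, 256), vessel_density = 0.12,
                        root_count = 6, branch_prob = 0.015,
                        width_mean = 3, width_sd = 0.6, tortuosity = 0.18,
                        background_rgb_mean = c(180, 95, 45),
                        background_rgb_sd = c(10, 8, 6),
                        green_shift = 0, blue_shift = 0,
                        noise_sd = 5, seed = 1) {
  if (n_images < 1) stop("n_images must be >= 1")
  if (vessel_density < 0 || vessel_density >= 0.5)
    stop("vessel_density must lie in [0, 0.5)")
  if (width_mean < 1) stop("width_mean must be >= 1")
  if (length(image_size) != 2L || any(image_size < 64))
    stop("image_size must be (height, width) with both >= 64")
  if (length(background_rgb_mean) != 3L || length(background_rgb_sd) != 3L)
    stop("background_rgb_mean and background_rgb_sd must be length-3 vectors")
  structure(list(group_name = group_name, n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 vessel_density = vessel_density,
                 root_count = as.integer(root_count),
                 branch_prob = branch_prob,
                 width_mean = width_mean, width_sd = width_sd,
                 tortuosity = tortuosity,
                 background_rgb_mean = as.numeric(background_rgb_mean),
                 background_rgb_sd = as.numeric(background_rgb_sd),
                 green_shift = green_shift, blue_shift = blue_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Load a shipped (or user) cohort preset
#'
#' Presets are YAML files of [cohort_spec()] fields. The package ships
#' `"healthy"` and `"pathological"` presets under `inst/presets/`.
#'
#' @param name preset name (without extension) or a path to a YAML file.
#' @param ... overrides applied on top of the preset fields (e.g. `seed`).
#' @return A [cohort_spec()].
#' @export
load_preset <- function(name, ...) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "fundustex")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset: ", name)
  fields <- yaml::read_yaml(path)
  over <- list(...)
  fields[names(over)] <- over
  do.call(cohort_spec, fields)
}

# disc stamp offsets for a vessel of the given width (diameter = width px)
disc_offsets <- function(width) {
  r <- max(width / 2, 0.5)
  ri <- floor(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic vessel tree
#'
#' Stochastic branching random walk: `root_count` walkers start on a nominal
#' optic-disc location with outward headings; each step advances 1 px with
#' the heading jittered by `N(0, tortuosity^2)`, stamps a disc of the
#' walker's width, and spawns a child with probability `branch_prob` (child
#' width = 0.8 x parent width, children below 1 px are not spawned). Walkers
#' die at the field boundary; when the whole population dies before the
#' target density is reached, a fresh batch of roots is seeded so that the
#' measured density lands within the target band. Growth stops when the
#' vessel-pixel fraction of the field reaches `vessel_density`, or at the
#' global step cap (in which case the mask carries a `density_warning`
#' attribute and a warning is raised).
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param max_steps global walker-step cap guarding against unreachable
#'   densities.
#' @return A [vessel_mask] strictly inside the circular field, with
#'   attributes `fov` (logical field mask), `density` (measured vessel
#'   fraction of the field) and `density_warning`.
#' @export
generate_vessel_tree <- function(spec, seed = spec$seed, max_steps = 100000) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  fov <- circular_fov(h, w)
  fov_area <- sum(fov)
  mask <- matrix(0L, h, w)
  if (spec$vessel_density <= 0) {
    out <- vessel_mask(mask)
    attr(out, "fov") <- fov
    attr(out, "density") <- 0
    attr(out, "density_warning") <- FALSE
    return(out)
  }

  out <- with_seed(seed, {
    radius <- 0.48 * min(h, w)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    disc_r <- cy; disc_c <- cx - 0.55 * radius  # nominal optic disc, nasal side

    spawn_roots <- function(n) {
      list(r = disc_r + stats::rnorm(n, 0, 2),
           c = disc_c + stats::rnorm(n, 0, 2),
           heading = stats::rnorm(n, 0, 1.1),   # fan out toward the field
           width = pmax(1, stats::rnorm(n, spec$width_mean, spec$width_sd)))
    }

    wk <- spawn_roots(spec$root_count)
    offsets_cache <- list()
    get_off <- function(width) {
      key <- sprintf("%.1f", width)
      if (is.null(offsets_cache[[key]]))
        offsets_cache[[key]] <<- disc_offsets(width)
      offsets_cache[[key]]
    }

    steps <- 0L
    frac <- 0
    warned <- FALSE
    repeat {
      nw <- length(wk$r)
      if (nw == 0L) {
        if (frac >= spec$vessel_density || steps >= max_steps) break
        wk <- spawn_roots(spec$root_count)
        next
      }
      wk$heading <- wk$heading + stats::rnorm(nw, 0, spec$tortuosity)
      wk$r <- wk$r + sin(wk$heading)
      wk$c <- wk$c + cos(wk$heading)
      ri <- as.integer(round(wk$r)); ci <- as.integer(round(wk$c))
      alive <- ri >= 1L & ri <= h & ci >= 1L & ci <= w
      alive[alive] <- fov[cbind(ri[alive], ci[alive])]
      for (k in which(alive)) {
        off <- get_off(wk$width[k])
        rr <- ri[k] + off$dr
        cc <- ci[k] + off$dc
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (any(ok)) {
          idx <- cbind(rr[ok], cc[ok])
          idx <- idx[fov[idx], , drop = FALSE]
          mask[idx] <- 1L          # in place: mask is not aliased here
        }
      }
      steps <- steps + nw

      # branching: child inherits position, deflected heading, tapered width
      kids <- which(alive & stats::runif(nw) < spec$branch_prob &
                      wk$width * 0.8 >= 1)
      if (length(kids) > 0L) {
        sign <- ifelse(stats::runif(length(kids)) < 0.5, -1, 1)
        wk$r <- c(wk$r[alive], wk$r[kids])
        wk$c <- c(wk$c[alive], wk$c[kids])
        wk$heading <- c(wk$heading[alive],
                        wk$heading[kids] + sign * stats::runif(length(kids), 0.3, 0.9))
        wk$width <- c(wk$width[alive], wk$width[kids] * 0.8)
      } else {
        wk <- lapply(wk, function(v) v[alive])
      }

      frac <- sum(mask) / fov_area
      if (frac >= spec$vessel_density) break
      if (steps >= max_steps) {
        warned <- TRUE
        break
      }
    }
    if (frac < spec$vessel_density * 0.9) warned <- TRUE
    list(mask = mask, frac = frac, warned = warned)
  })

  if (out$warned)
    warning(sprintf("target vessel density %.3f not reached (got %.3f) within the step cap",
                    spec$vessel_density, out$frac))
  m <- vessel_mask(out$mask)
  attr(m, "fov") <- fov
  attr(m, "density") <- out$frac
  attr(m, "density_warning") <- out$warned
  m
}

#' Render a synthetic fundus image over a vessel mask
#'
#' Background pixels are drawn from
#' `N(background_rgb_mean + (0, green_shift, blue_shift), background_rgb_sd^2)`;
#' vessel pixels are set to 0.55 x the (shifted) background mean channel-wise,
#' which makes them dark as in real fundus photographs; `N(0, noise_sd^2)`
#' noise is added to every in-field pixel; pixels outside the circular field
#' are 0. The result is rounded and clipped to 8-bit.
#'
#' @param mask a [vessel_mask] with dimensions matching `spec$image_size`.
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param id image identifier attached to the output.
#' @return A [fundus_image] with the circular field as its `fov` attribute.
#' @export
render_fundus <- function(mask, spec, seed = spec$seed, id = "synthetic") {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  if (!identical(dim(mask), c(h, w)))
    stop("mask dimensions must match spec$image_size")
  fov <- attr(mask, "fov")
  if (is.null(fov)) fov <- circular_fov(h, w)
  shift <- c(0, spec$green_shift, spec$blue_shift)
  vessel <- mask == 1L

  px <- with_seed(seed, {
    arr <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      mu <- spec$background_rgb_mean[ch] + shift[ch]
      plane <- matrix(stats::rnorm(h * w, mu, spec$background_rgb_sd[ch]), h, w)
      plane[vessel] <- mu * 0.55
      if (spec$noise_sd > 0)
        plane <- plane + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      plane[!fov] <- 0
      arr[, , ch] <- plane
    }
    arr
  })
  fundus_image(pmin(pmax(floor(px + 0.5), 0), 255), id = id,
               group = spec$group_name, fov = fov)
}

#' Generate a seeded synthetic cohort
#'
#' Produces `spec$n_images` image/mask pairs. Each image draws from its own
#' RNG sub-stream derived from the master seed by fixed strides, so the
#' cohort is reproducible as a whole while images are mutually independent.
#'
#' @param spec a [cohort_spec()].
#' @return List of `synthetic_sample` objects, each a list with `image`
#'   (a [fundus_image]), `mask` (the ground-truth [vessel_mask]), `spec_ref`
#'   (the group label) and `seed` (the sample's sub-seed).
#' @export
generate_cohort <- function(spec) {
  lapply(seq_len(spec$n_images), function(i) {
    tree_seed <- derive_seed(spec$seed, i)
    render_seed <- derive_seed(spec$seed, i, stride = 500009L)
    mask <- generate_vessel_tree(spec, seed = tree_seed)
    img <- render_fundus(mask, spec, seed = render_seed,
                         id = sprintf("%s_%03d", spec$group_name, i))
    structure(list(image = img, mask = mask, spec_ref = spec$group_name,
                   seed = tree_seed),
              class = "synthetic_sample")
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes each image and ground-truth mask as 8-bit PNG and a cohort
#' manifest CSV with columns `file`, `mask_file`, `group`, `seed` (the
#' manifest format consumed by [run_study()]).
#'
#' @param samples list of samples from [generate_cohort()] (cohorts of
#'   several groups may be concatenated).
#' @param dir output directory, created if needed.
#' @return Invisibly, the manifest data.frame.
#' @export
save_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    id <- attr(s$image, "id")
    img_file <- file.path(dir, paste0(id, ".png"))
    mask_file <- file.path(dir, paste0(id, "_mask.png"))
    write_fundus_png(s$image, img_file)
    write_mask_png(s$mask, mask_file)
    data.frame(file = img_file, mask_file = mask_file,
               group = s$spec_ref, seed = s$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
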