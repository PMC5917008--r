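# Synthetic 3-D two-channel phantoms of microglia-like cells with voxel-level
# ground truth. Cells are a soma ball plus random-walk tubes (rasterized as
# dense unions of spheres along the walk), a nucleus ball in the nuclear
# channel, and additive Gaussian noise clipped to the bit range. The two
# presets span the morphological continuum between the ramified/surveilling
# and the amoeboid/activated phenotype.

#' Synthetic cell specification
#'
#' @param soma_radius_um soma ball radius.
#' @param n_primary_branches number of primary branches leaving the soma.
#' @param branch_length_um `c(mean, sd)` of primary branch length.
#' @param branch_radius_um tube radius.
#' @param bifurcation_probability probability of spawning a daughter branch
#'   per 5 um walked.
#' @param tortuosity directional jitter per um walked (0 = straight).
#' @param nucleus_radius_um nucleus ball radius (< soma radius).
#' @param intensity_fg,intensity_bg foreground/background intensity levels.
#' @param placement_um optional `(z, y, x)` soma centre in micrometres.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(soma_radius_um, n_primary_branches,
                                branch_length_um, branch_radius_um,
                                bifurcation_probability, tortuosity,
                                nucleus_radius_um,
                                intensity_fg = 180, intensity_bg = 20,
                                placement_um = NULL) {
  stopifnot(soma_radius_um > 0, branch_radius_um > 0,
            nucleus_radius_um > 0, nucleus_radius_um < soma_radius_um,
            bifurcation_probability >= 0, bifurcation_probability <= 1,
            tortuosity >= 0)
  structure(
    list(soma_radius_um = soma_radius_um,
         n_primary_branches = as.integer(n_primary_branches),
         branch_length_um = branch_length_um,
         branch_radius_um = branch_radius_um,
         bifurcation_probability = bifurcation_probability,
         tortuosity = tortuosity,
         nucleus_radius_um = nucleus_radius_um,
         intensity_fg = intensity_fg,
         intensity_bg = intensity_bg,
         placement_um = placement_um),
    class = "synthetic_cell_spec")
}

#' Ramified (surveilling) phenotype preset
#'
#' Small soma (3 um), 4-6 long tortuous primary branches (20 +/- 5 um).
#'
#' @param seed integer seed; the same seed gives the identical spec.
#' @return A [synthetic_cell_spec()].
#' @export
ramified_spec <- function(seed) {
  with_seed(seed, {
    synthetic_cell_spec(
      soma_radius_um = 3,
      n_primary_branches = sample(4:6, 1),
      branch_length_um = c(20, 5),
      branch_radius_um = 0.7,
      bifurcation_probability = 0.15,
      tortuosity = 0.35,
      nucleus_radius_um = 1.5)
  })
}

#' Amoeboid (activated) phenotype preset
#'
#' Large soma (6 um), 0-2 short branches (5 +/- 2 um).
#'
#' @param seed integer seed; the same seed gives the identical spec.
#' @return A [synthetic_cell_spec()].
#' @export
amoeboid_spec <- function(seed) {
  with_seed(seed, {
    synthetic_cell_spec(
      soma_radius_um = 6,
      n_primary_branches = sample(0:2, 1),
      branch_length_um = c(5, 2),
      branch_radius_um = 1.0,
      bifurcation_probability = 0.05,
      tortuosity = 0.2,
      nucleus_radius_um = 2.5)
  })
}

# Linear indices of a ball in a (z, y, x) grid, physical radius, anisotropic.
ball_indices <- function(center_um, radius_um, dims, vs) {
  lo <- pmax(1L, floor(center_um / vs - radius_um / vs) + 1L)
  hi <- pmin(dims, ceiling(center_um / vs + radius_um / vs) + 1L)
  if (any(lo > hi)) return(integer(0))
  z <- (lo[1]:hi[1] - 1) * vs[1] - center_um[1]
  y <- (lo[2]:hi[2] - 1) * vs[2] - center_um[2]
  x <- (lo[3]:hi[3] - 1) * vs[3] - center_um[3]
  g <- expand.grid(z = z, y = y, x = x)
  keep <- g$z^2 + g$y^2 + g$x^2 <= radius_um^2
  gi <- expand.grid(i1 = lo[1]:hi[1], i2 = lo[2]:hi[2], i3 = lo[3]:hi[3])
  lin <- gi$i1 + (gi$i2 - 1L) * dims[1] + (gi$i3 - 1L) * dims[1] * dims[2]
  lin[keep]
}

# random unit direction, mildly biased toward the xy plane (thin stacks)
random_direction <- function(z_scale = 0.4) {
  v <- rnorm(3)
  v[1] <- v[1] * z_scale
  v / sqrt(sum(v^2))
}

# Walk one branch; returns list(points = matrix of (z,y,x) um, tips, forks).
walk_branch <- function(start, direction, length_um, spec, depth = 1L) {
  step <- spec$branch_radius_um / 2
  n_steps <- max(2L, ceiling(length_um / step))
  pts <- matrix(NA_real_, n_steps, 3)
  p <- start
  dir <- direction
  walked <- 0
  since_fork <- 0
  forks <- list()
  n_forks <- 0L
  for (i in seq_len(n_steps)) {
    p <- p + dir * step
    pts[i, ] <- p
    walked <- walked + step
    since_fork <- since_fork + step
    jit <- rnorm(3) * spec$tortuosity * sqrt(step)
    dir <- dir + jit
    dir <- dir / sqrt(sum(dir^2))
    if (since_fork >= 5 && depth < 3L) {
      since_fork <- 0
      if (runif(1) < spec$bifurcation_probability) {
        nd <- dir + rnorm(3) * 0.6
        nd <- nd / sqrt(sum(nd^2))
        forks[[length(forks) + 1L]] <-
          walk_branch(p, nd, (length_um - walked) * 0.7, spec, depth + 1L)
        n_forks <- n_forks + 1L
      }
    }
  }
  sub_pts <- lapply(forks, `[[`, "points")
  list(points = pts,
       polyline = pts,
       sub = forks,
       all_points = do.call(rbind, c(list(pts), sub_pts)),
       n_tips = 1L + sum(vapply(forks, `[[`, integer(1), "n_tips")),
       n_forks = n_forks + sum(vapply(forks, `[[`, integer(1), "n_forks")))
}

#' Render a synthetic two-channel stack with ground truth
#'
#' Draws each cell as a soma ball plus random-walk tubes (spheres rasterized
#' along the walk at half-radius spacing, so the union is dense), puts the
#' nucleus ball into the nuclear channel, and adds seeded Gaussian noise
#' (standard deviation = `noise_sd_fraction` x the foreground-background
#' dynamic range) clipped to the bit range. Deterministic per seed.
#'
#' @param specs list of [synthetic_cell_spec()] with `placement_um` set.
#' @param dims_um stack extent `(z, y, x)` in micrometres.
#' @param voxel_size `(dz, dy, dx)` in micrometres; default the acquisition
#'   default `c(0.4, 0.2, 0.2)`.
#' @param noise_sd_fraction i.i.d. noise level as a fraction of dynamic
#'   range.
#' @param texture_sd_fraction amplitude of the smooth, z-correlated
#'   background texture as a fraction of dynamic range; the default
#'   `2.5 * noise_sd_fraction` keeps neighbouring-slice correlations in the
#'   ~0.85 range typical of usable tissue slices. Set 0 for a pure two-level
#'   phantom.
#' @param seed integer seed.
#' @param bit_depth 8 (default) or 16.
#' @return A list: `stack` (an [image_stack()]) and `truth` (class
#'   `ground_truth`): per-voxel `cell_id` volume, `compartment` volume
#'   (1 branch, 2 soma, 3 nucleus), per-cell tibble `cells` (placement,
#'   phenotype fields, true primary/end/bifurcation counts), and skeleton
#'   `polylines` per cell.
#' @export
render_stack <- function(specs, dims_um, voxel_size = c(0.4, 0.2, 0.2),
                         noise_sd_fraction = 0.05,
                         texture_sd_fraction = 2.5 * noise_sd_fraction,
                         seed = 1, bit_depth = 8L) {
  stopifnot(all(voxel_size > 0))
  dims <- pmax(2L, as.integer(round(dims_um / voxel_size)))
  place <- t(vapply(specs, function(s) {
    if (is.null(s$placement_um)) {
      stop("every spec needs placement_um (see place_cells_grid)",
           call. = FALSE)
    }
    s$placement_um
  }, numeric(3)))
  if (length(specs) > 1L) {
    for (i in seq_len(length(specs) - 1L)) {
      for (j in (i + 1L):length(specs)) {
        d <- sqrt(sum((place[i, ] - place[j, ])^2))
        if (d < specs[[i]]$soma_radius_um + specs[[j]]$soma_radius_um) {
          stop("somata of cells ", i, " and ", j, " overlap", call. = FALSE)
        }
      }
    }
  }
  vs <- voxel_size
  with_seed(seed, {
    membrane <- array(0L, dim = dims)
    nuclear <- array(0L, dim = dims)
    cell_id <- array(0L, dim = dims)
    compartment <- array(0L, dim = dims)
    cells <- list()
    polylines <- list()
    for (ci in seq_along(specs)) {
      s <- specs[[ci]]
      ctr <- place[ci, ]
      soma_idx <- ball_indices(ctr, s$soma_radius_um, dims, vs)
      branch_idx <- integer(0)
      n_tips <- 0L
      n_forks <- 0L
      polys <- list()
      if (s$n_primary_branches > 0L) {
        for (b in seq_len(s$n_primary_branches)) {
          dir <- random_direction()
          len <- max(1, rnorm(1, s$branch_length_um[1], s$branch_length_um[2]))
          start <- ctr + dir * s$soma_radius_um * 0.8
          br <- walk_branch(start, dir, len, s)
          pts <- br$all_points
          for (k in seq_len(nrow(pts))) {
            branch_idx <- c(branch_idx,
                            ball_indices(pts[k, ], s$branch_radius_um, dims,
                                         vs))
          }
          polys[[b]] <- br$polyline
          n_tips <- n_tips + br$n_tips
          n_forks <- n_forks + br$n_forks
        }
        branch_idx <- unique(branch_idx)
      }
      nuc_idx <- ball_indices(ctr, s$nucleus_radius_um, dims, vs)
      body <- unique(c(soma_idx, branch_idx))
      membrane[body] <- 1L
      nuclear[nuc_idx] <- 1L
      cell_id[body] <- ci
      compartment[branch_idx] <- 1L
      compartment[soma_idx] <- 2L
      compartment[nuc_idx] <- 3L
      cells[[ci]] <- tibble::tibble(
        cell_id = ci,
        z_um = ctr[1], y_um = ctr[2], x_um = ctr[3],
        soma_radius_um = s$soma_radius_um,
        n_primary_branches = s$n_primary_branches,
        n_end_points = n_tips,
        n_bifurcations = n_forks)
      polylines[[ci]] <- polys
    }
    maxv <- 2^bit_depth - 1
    rng <- specs[[1]]$intensity_fg - specs[[1]]$intensity_bg
    render_channel <- function(fgmask) {
      base <- ifelse(fgmask > 0L, specs[[1]]$intensity_fg,
                     specs[[1]]$intensity_bg)
      if (texture_sd_fraction > 0) {
        # smooth 3-D-correlated background texture (tissue autofluorescence),
        # drawn independently per channel: neighbouring slices of real
        # stacks correlate highly, which is what slice QC relies on
        tex <- gauss3(array(rnorm(prod(dims)), dim = dims), c(4, 4, 4))
        base <- base + tex / stats::sd(tex) * texture_sd_fraction * rng
      }
      if (noise_sd_fraction > 0) {
        base <- base + rnorm(length(base), 0, noise_sd_fraction * rng)
      }
      array(pmin(maxv, pmax(0, round(base))), dim = dims)
    }
    vox <- array(0, dim = c(2L, dims))
    vox[1, , , ] <- render_channel(membrane)
    vox[2, , , ] <- render_channel(nuclear)
    truth <- structure(
      list(cell_id = cell_id,
           compartment = compartment,
           cells = dplyr::bind_rows(cells),
           polylines = polylines,
           voxel_size = vs),
      class = "ground_truth")
    list(stack = image_stack(vox, vs, bit_depth = bit_depth),
         truth = truth)
  })
}

#' Grid placement of cell somata inside the exclusion margins
#'
#' Lays `k` soma centres on a jittered square grid in the central z plane,
#' keeping at least `margin_xy_um` / `margin_z_um` to the borders and at
#' least `min_separation_um` between centres.
#'
#' @param k number of cells.
#' @param dims_um stack extent `(z, y, x)`.
#' @param margin_xy_um,margin_z_um border margins, defaults 15 and 8.
#' @param min_separation_um minimum pairwise separation, default 16.
#' @param jitter_um random jitter applied to each grid point, default 1.
#' @param clearance_um extra distance beyond the margin (so jitter and
#'   centroid-measurement error cannot push a soma inside it), default 2.
#' @return A `k` x 3 matrix of `(z, y, x)` placements in micrometres.
#' @export
place_cells_grid <- function(k, dims_um, margin_xy_um = 15, margin_z_um = 8,
                             min_separation_um = 16, jitter_um = 1,
                             clearance_um = 2) {
  margin_xy_um <- margin_xy_um + clearance_um + jitter_um
  usable <- c(dims_um[2], dims_um[3]) - 2 * margin_xy_um
  n_side <- ceiling(sqrt(k))
  if (n_side > 1 && any(usable / (n_side - 1) < min_separation_um)) {
    stop("stack too small for ", k, " cells at this separation",
         call. = FALSE)
  }
  coords1 <- function(n, extent) {
    if (n == 1L) {
      extent / 2
    } else {
      margin_xy_um + (seq_len(n) - 1) * (extent - 2 * margin_xy_um) / (n - 1)
    }
  }
  gy <- coords1(n_side, dims_um[2])
  gx <- coords1(n_side, dims_um[3])
  g <- expand.grid(y = gy, x = gx)[seq_len(k), , drop = FALSE]
  zc <- dims_um[1] / 2
  out <- cbind(z = rep(zc, k),
               y = g$y + runif(k, -jitter_um, jitter_um),
               x = g$x + runif(k, -jitter_um, jitter_um))
  unname(as.matrix(out))
}

#' Render a phantom benchmark cohort
#'
#' Renders `n_ramified` + `n_amoeboid` cells across single-phenotype stacks
#' of `cells_per_stack` cells each, with ground truth, at an isotropic
#' phantom resolution chosen for desk-scale runtimes.
#'
#' @param n_ramified,n_amoeboid cells per phenotype, defaults 20 each.
#' @param cells_per_stack default 4.
#' @param dims_um per-stack extent, default `c(20, 66, 66)`.
#' @param voxel_size default `c(0.5, 0.5, 0.5)` (phantom resolution; branch
#'   tubes stay ~3 voxels across).
#' @param noise_sd_fraction default 0.05.
#' @param seed base seed; stack `i` uses `seed * 1000 + i`.
#' @return A list of elements `list(stack, truth, group)`.
#' @export
phantom_cohort <- function(n_ramified = 20, n_amoeboid = 20,
                           cells_per_stack = 4,
                           dims_um = c(20, 66, 66),
                           voxel_size = c(0.5, 0.5, 0.5),
                           noise_sd_fraction = 0.05, seed = 1) {
  mk <- function(n, group, preset, seed_off) {
    n_stacks <- ceiling(n / cells_per_stack)
    lapply(seq_len(n_stacks), function(si) {
      k <- min(cells_per_stack, n - (si - 1L) * cells_per_stack)
      s <- seed * 1000 + seed_off + si
      specs <- with_seed(s, {
        pl <- place_cells_grid(k, dims_um)
        lapply(seq_len(k), function(i) {
          sp <- preset(s * 100 + i)
          sp$placement_um <- pl[i, ]
          sp
        })
      })
      r <- render_stack(specs, dims_um, voxel_size, noise_sd_fraction,
                        seed = s)
      r$group <- group
      r
    })
  }
  c(mk(n_ramified, "ramified", ramified_spec, 0L),
    mk(n_amoeboid, "amoeboid", amoeboid_spec, 500L))
}
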