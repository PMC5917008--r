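# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps stack generation deterministic without
# clobbering user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

vol_dim <- function(x) as.integer(dim(x))

# Wrappers around the compiled kernels that keep dim bookkeeping in one place.
edt3 <- function(mask, voxel_size) {
  d <- .edt_aniso(as.logical(mask), vol_dim(mask), as.numeric(voxel_size))
  array(d, dim = dim(mask))
}

cc3 <- function(mask, connectivity = 26L) {
  array(.cc_label(as.logical(mask), vol_dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

fill3 <- function(mask) {
  array(.fill_holes3d(as.logical(mask), vol_dim(mask)), dim = dim(mask))
}

dilate3 <- function(mask) {
  array(.dilate_box(as.logical(mask), vol_dim(mask)), dim = dim(mask))
}

erode3 <- function(mask) {
  array(.erode_box(as.logical(mask), vol_dim(mask)), dim = dim(mask))
}

gauss3 <- function(vol, sigma_vox) {
  array(.gauss_sep(as.numeric(vol), vol_dim(vol), as.numeric(sigma_vox)),
        dim = dim(vol))
}

# Otsu's between-class-variance threshold on a numeric vector (256-bin
# histogram over the observed range). Returns a cut value; values strictly
# above it are foreground.
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * (r[2] - r[1])
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w - mu)^2 / (w * (1 - w))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits. Used to fingerprint
# the feature roster so results can cite a roster version.
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # modular multiply by the FNV prime without exceeding double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
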