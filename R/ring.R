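# Radial-intensity quantification of T-cell rings around tumour-cell
# clusters, with synthetic image-pair generation and one-way ANOVA group
# comparison.
#
# Convention: images are numeric matrices (row, col), intensities >= 0;
# bright-field uses "high intensity = cell-dense" polarity (an inversion
# flag is provided since acquisition polarity varies).

#' Generate a synthetic co-culture image pair
#'
#' Fluorescence channel: a disc (the dye-labelled tumour-cell cluster)
#' plus Gaussian noise. Bright-field channel (cell-density convention):
#' the same disc plus an annular T-cell ring starting `ring_offset_um`
#' outside the disc edge. Deterministic per seed.
#'
#' @param cluster_radius_um Disc radius in micrometres (> 0).
#' @param ring_offset_um Gap between disc edge and inner ring edge.
#' @param ring_width_um Radial width of the ring.
#' @param ring_amplitude Ring intensity (0 disables the ring).
#' @param disc_amplitude_fl,disc_amplitude_bf Disc intensity per channel.
#' @param background Background intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param size_px Image side length in pixels (square).
#' @param pixel_size_um Micrometres per pixel.
#' @param centre_px Optional `(row, col)` centre; default image centre.
#' @param seed Integer seed.
#' @param group,replicate Metadata labels.
#' @return List of class `image_pair`: `bright_field`, `fluorescence`
#'   (matrices), `pixel_size_um`, `centre_px` (true centre used),
#'   `ring_radius_um` (radial centre of the ring), `group`, `replicate`.
#' @export
generate_cluster_image <- function(cluster_radius_um = 40,
                                   ring_offset_um = 5,
                                   ring_width_um = 15,
                                   ring_amplitude = 0.6,
                                   disc_amplitude_fl = 0.9,
                                   disc_amplitude_bf = 0.7,
                                   background = 0.05, noise_sd = 0.02,
                                   size_px = 256, pixel_size_um = 1.3,
                                   centre_px = NULL, seed = 1,
                                   group = "default", replicate = 1L) {
  if (cluster_radius_um <= 0) stop("cluster radius must be > 0",
                                   call. = FALSE)
  r_in <- cluster_radius_um + ring_offset_um
  r_out <- r_in + ring_width_um
  if (is.null(centre_px)) centre_px <- c(size_px, size_px) / 2 + 0.5
  if (r_out / pixel_size_um > min(centre_px - 1,
                                  size_px - centre_px)) {
    stop("cluster + ring geometry does not fit in the image",
         call. = FALSE)
  }
  d_um <- .radial_distance(size_px, size_px, centre_px) * pixel_size_um
  disc <- d_um <= cluster_radius_um
  ring <- d_um >= r_in & d_um <= r_out
  fl <- background + disc_amplitude_fl * disc
  bf <- background + disc_amplitude_bf * disc + ring_amplitude * ring
  if (noise_sd > 0) {
    withr::with_seed(.split_seed(seed, 40L), {
      fl <- fl + matrix(rnorm(size_px^2, 0, noise_sd), size_px)
      bf <- bf + matrix(rnorm(size_px^2, 0, noise_sd), size_px)
    })
  }
  structure(list(bright_field = pmax(bf, 0), fluorescence = pmax(fl, 0),
                 pixel_size_um = pixel_size_um, centre_px = centre_px,
                 ring_radius_um = (r_in + r_out) / 2, group = group,
                 replicate = replicate),
            class = "image_pair")
}

# Matrix of distances (in px) from `centre` (row, col; 1-based).
.radial_distance <- function(nr, nc, centre) {
  dr <- (seq_len(nr) - centre[1])^2
  dc <- (seq_len(nc) - centre[2])^2
  sqrt(outer(dr, dc, "+"))
}

#' Gaussian smoothing with reflective boundary
#'
#' Separable Gaussian convolution with `sigma_px = sigma_um /
#' pixel_size_um` (kernel half-width 4 sigma, normalised to sum 1).
#' `sigma_um = 0` returns the image unchanged. Reflective padding avoids
#' the edge darkening that would bias radial profiles.
#'
#' @param image Numeric matrix (finite values).
#' @param sigma_um Gaussian sigma in micrometres (the screen used
#'   14.4 um).
#' @param pixel_size_um Micrometres per pixel.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_image <- function(image, sigma_um = 14.4, pixel_size_um = 1.3) {
  if (!all(is.finite(image))) stop("non-finite pixels", call. = FALSE)
  if (sigma_um < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma_um == 0) return(image)
  sigma <- sigma_um / pixel_size_um
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  reflect <- function(p, n) {  # symmetric reflection, any overhang
    q <- (p - 1L) %% (2L * n)
    ifelse(q < n, q + 1L, 2L * n - q)
  }
  conv1 <- function(M) {  # along rows (dimension 1), reflective
    n <- nrow(M)
    idx <- reflect(seq.int(1L - h, n + h), n)
    P <- M[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(M))
    for (t in seq_along(k)) {
      out <- out + k[t] * P[(t - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(image))))
}

#' Radial intensity profile
#'
#' Bin `k` (0-based) is the mean intensity over pixels whose distance
#' from the centre lies in `[k * w, (k + 1) * w)` micrometres. Bins with
#' no pixels are `NA` and flagged; a max radius reaching beyond the
#' nearest image edge truncates with a warning flag rather than an
#' error.
#'
#' @param image Numeric matrix.
#' @param centre `(row, col)` centre in pixels (may be fractional).
#' @param max_radius_um Outer profile radius.
#' @param bin_width_um Radial bin width (default: one pixel-equivalent).
#' @param pixel_size_um Micrometres per pixel.
#' @return data.frame of class `radial_profile`: `bin` (0-based),
#'   `r_mid_um`, `mean_intensity`, `n_pixels`, `empty`; truncation flag
#'   in `attr(, "truncated")`.
#' @export
radial_profile <- function(image, centre, max_radius_um,
                           bin_width_um = NULL, pixel_size_um = 1.3) {
  nr <- nrow(image); nc <- ncol(image)
  if (centre[1] < 1 || centre[1] > nr || centre[2] < 1 || centre[2] > nc) {
    stop("centre outside image", call. = FALSE)
  }
  if (is.null(bin_width_um)) bin_width_um <- pixel_size_um
  edge_um <- min(centre[1] - 1, nr - centre[1],
                 centre[2] - 1, nc - centre[2]) * pixel_size_um
  truncated <- max_radius_um > edge_um
  d_um <- .radial_distance(nr, nc, centre) * pixel_size_um
  nbins <- ceiling(max_radius_um / bin_width_um)
  bin <- floor(d_um / bin_width_um)
  sel <- bin < nbins
  sums <- tapply(image[sel], bin[sel], sum)
  cnts <- tapply(rep(1, sum(sel)), bin[sel], sum)
  mean_i <- rep(NA_real_, nbins); npix <- rep(0L, nbins)
  ib <- as.integer(names(sums)) + 1L
  mean_i[ib] <- sums / cnts
  npix[ib] <- as.integer(cnts)
  out <- data.frame(bin = seq_len(nbins) - 1L,
                    r_mid_um = (seq_len(nbins) - 0.5) * bin_width_um,
                    mean_intensity = mean_i, n_pixels = npix,
                    empty = npix == 0L)
  attr(out, "truncated") <- truncated
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Min-max normalise two profiles and subtract
#'
#' Each profile is mapped by `(x - min) / (max - min)`; the difference
#' profile is normalised bright-field minus normalised fluorescence and
#' the ring statistic is its maximum over bins (exact ties, as arise on
#' noise-free plateaus, resolve to the middle tied bin). A constant profile
#' (max = min) cannot be normalised: it is set to all-zeros and the
#' cluster flagged degenerate.
#'
#' @param bf_profile,fl_profile Numeric vectors or [radial_profile()]
#'   tables of equal bin count.
#' @param subtract_order `"bf_minus_fl"` (default) or `"fl_minus_bf"`.
#' @return List: `difference` (per-bin), `max_intensity_difference`,
#'   `argmax_bin` (0-based), `degenerate`.
#' @export
normalize_and_subtract <- function(bf_profile, fl_profile,
                                   subtract_order = c("bf_minus_fl",
                                                      "fl_minus_bf")) {
  subtract_order <- match.arg(subtract_order)
  as_vec <- function(p) {
    if (inherits(p, "radial_profile")) p$mean_intensity else as.numeric(p)
  }
  bf <- as_vec(bf_profile); fl <- as_vec(fl_profile)
  if (length(bf) != length(fl)) stop("profiles have different bin counts",
                                     call. = FALSE)
  degenerate <- FALSE
  norm <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) { degenerate <<- TRUE; return(rep(0, length(x))) }
    (x - rng[1]) / diff(rng)
  }
  nb <- norm(bf); nf <- norm(fl)
  d <- if (subtract_order == "bf_minus_fl") nb - nf else nf - nb
  mx <- max(d, na.rm = TRUE)
  # a noise-free annulus yields an exact plateau of tied maxima; take the
  # middle tied bin (plain which.max when ties are broken by noise)
  tied <- which(!is.na(d) & d >= mx - 1e-12)
  argmax <- tied[ceiling(length(tied) / 2)]
  list(difference = d, max_intensity_difference = mx,
       argmax_bin = argmax - 1L, degenerate = degenerate)
}

# Otsu threshold on a 256-bin histogram of [min, max].
.otsu <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), 256L)
  p <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  w <- cumsum(p); mu <- cumsum(p * mids); mt <- mu[256L]
  sb <- (mt * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# 4-connected component labelling of a logical matrix (two-pass
# union-find).
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1L) lab[i - 1L, j] else 0L
      left <- if (j > 1L) lab[i, j - 1L] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        lab[i, j] <- ru
        if (ru != rl) parent[rl] <- ru
      } else {
        lab[i, j] <- max(up, left)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relabel <- match(roots, unique(roots))
    pos <- lab > 0L
    lab[pos] <- relabel[lab[pos]]
  }
  lab
}

#' Detect the tumour-cluster centre in a fluorescence image
#'
#' Thresholds the image (Otsu), labels 4-connected components, keeps the
#' largest, and returns its intensity-weighted centroid.
#'
#' @param fluorescence Numeric matrix.
#' @param smooth_sigma_um Pre-smoothing sigma (0 to disable).
#' @param pixel_size_um Micrometres per pixel.
#' @return `(row, col)` centre in pixels.
#' @export
detect_cluster_centre <- function(fluorescence, smooth_sigma_um = 0,
                                  pixel_size_um = 1.3) {
  img <- if (smooth_sigma_um > 0) {
    smooth_image(fluorescence, smooth_sigma_um, pixel_size_um)
  } else fluorescence
  thr <- .otsu(as.vector(img))
  mask <- img > thr
  if (!any(mask)) stop("no cluster found", call. = FALSE)
  lab <- .label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (!length(sizes)) stop("no cluster found", call. = FALSE)
  big <- which.max(sizes)
  sel <- lab == big
  w <- img[sel]
  rows <- row(img)[sel]; cols <- col(img)[sel]
  c(sum(rows * w) / sum(w), sum(cols * w) / sum(w))
}

#' Full per-cluster radial pipeline
#'
#' Smooths both channels (sigma 14.4 um by default, as in the screen),
#' locates the cluster centre on the fluorescence channel (unless given),
#' computes both radial profiles, normalises and subtracts them.
#'
#' @param pair An `image_pair`.
#' @param sigma_um Smoothing sigma in micrometres.
#' @param max_radius_um Profile radius; default 3x the detected disc
#'   extent is approximated as 40% of the image half-width when not
#'   given.
#' @param bin_width_um Radial bin width (default one pixel).
#' @param centre Optional `(row, col)` centre override.
#' @param invert_bright_field Set `TRUE` when cell-dense regions are dark
#'   in the bright-field channel.
#' @param subtract_order Passed to [normalize_and_subtract()].
#' @return List of class `cluster_profile`: `centre`, per-channel
#'   profiles, `difference`, `max_intensity_difference`, `argmax_bin`,
#'   `r_argmax_um`, `degenerate`, `group`, `replicate`.
#' @export
cluster_profile <- function(pair, sigma_um = 14.4, max_radius_um = NULL,
                            bin_width_um = NULL, centre = NULL,
                            invert_bright_field = FALSE,
                            subtract_order = "bf_minus_fl") {
  px <- pair$pixel_size_um
  bf <- pair$bright_field
  if (invert_bright_field) bf <- max(bf) - bf
  bf <- smooth_image(bf, sigma_um, px)
  fl <- smooth_image(pair$fluorescence, sigma_um, px)
  if (is.null(centre)) centre <- detect_cluster_centre(fl)
  if (is.null(max_radius_um)) {
    max_radius_um <- min(centre[1] - 1, nrow(bf) - centre[1],
                         centre[2] - 1, ncol(bf) - centre[2]) * px
  }
  pb <- radial_profile(bf, centre, max_radius_um, bin_width_um, px)
  pf <- radial_profile(fl, centre, max_radius_um, bin_width_um, px)
  ns <- normalize_and_subtract(pb, pf, subtract_order)
  structure(list(centre = centre, bf_profile = pb, fl_profile = pf,
                 difference = ns$difference,
                 max_intensity_difference = ns$max_intensity_difference,
                 argmax_bin = ns$argmax_bin,
                 r_argmax_um = pb$r_mid_um[ns$argmax_bin + 1L],
                 degenerate = ns$degenerate,
                 group = pair$group, replicate = pair$replicate),
            class = "cluster_profile")
}

#' One-way ANOVA with Tukey HSD on per-cluster statistics
#'
#' Standard between/within sum-of-squares ANOVA over groups of
#' max-intensity-difference statistics, with Tukey honest-significant-
#' difference adjusted pairwise p-values (studentized range). Degenerate
#' inputs are defined explicitly: zero between-group variation gives
#' `F = 0, p = 1`; zero within-group variation with non-zero
#' between-group variation gives `F = Inf, p = 0`.
#'
#' @param statistics Named list: group -> numeric vector of per-cluster
#'   statistics (>= 2 groups, each >= 2 values).
#' @return List of class `anova_report`: `F`, `p`, `df_between`,
#'   `df_within`, `group_means`, `pairwise` (data.frame with `diff` and
#'   Tukey-adjusted `p_adj`).
#' @export
compare_groups <- function(statistics) {
  if (length(statistics) < 2L) stop("need >= 2 groups", call. = FALSE)
  ni <- vapply(statistics, length, integer(1))
  if (any(ni < 2L)) stop("every group needs >= 2 observations",
                         call. = FALSE)
  x <- unlist(statistics, use.names = FALSE)
  g <- rep(names(statistics), ni)
  N <- length(x); k <- length(statistics)
  means <- vapply(statistics, mean, numeric(1))
  gm <- mean(x)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  dfb <- k - 1L; dfw <- N - k
  msw <- ssw / dfw
  if (ssb <= .Machine$double.eps * sum(x^2 + 1)) {
    Fv <- 0; p <- 1
  } else if (msw == 0) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ssb / dfb) / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(statistics), 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   diff = means[pairs[2L, ]] - means[pairs[1L, ]],
                   stringsAsFactors = FALSE)
  se <- sqrt(msw / 2 * (1 / ni[pairs[1L, ]] + 1 / ni[pairs[2L, ]]))
  q <- abs(pw$diff) / se
  pw$p_adj <- ifelse(is.nan(q) | se == 0,
                     ifelse(abs(pw$diff) > 0, 0, 1),
                     stats::ptukey(q, k, dfw, lower.tail = FALSE))
  row.names(pw) <- NULL
  structure(list(F = Fv, p = p, df_between = dfb, df_within = dfw,
                 group_means = means, pairwise = pw),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("<anova_report> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Read / write a grayscale image as PNG
#'
#' Intensities are clipped to [0, 1] on write (8-bit grayscale PNG).
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `read_image_png`: numeric matrix in [0, 1];
#'   `write_image_png`: `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
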