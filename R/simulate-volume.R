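#' Parameters for the synthetic cardiomyocyte volume generator
#'
#' Defines the statistical structure of a synthetic cardiomyocyte label
#' volume: overall mitochondrial volume fraction, the voxel-share mix of
#' the three subpopulations (SSM under the sarcolemma, IFM in rows
#' between myofibril slabs, PNM against the nuclear envelope), the
#' oval/irregular shape mix and tubular-projection probability per
#' subtype, projection and nanotunnel dimensions, and object sizes.
#'
#' Defaults reproduce wild-type myocardium conditions: 30.2 % mito
#' fraction, subtype shares 15.3/80.1/4.7 % (SSM/IFM/PNM), an IFM
#' oval:irregular mix of 69:31, projection lengths 0.574 +/- 0.415 um
#' with tip widths 0.220 +/- 0.068 um, and mean mitochondrion volumes of
#' 7.23/7.29/3.70 x 10^8 nm^3 per subtype.
#'
#' @param target_mito_fraction mitochondrial share of the cardiomyocyte
#'   volume, in `[0, 1]`.
#' @param subtype_mix named proportions (SSM, IFM, PNM) of mitochondrial
#'   voxel volume; must sum to 1.
#' @param shape_mix per-subtype named proportions of `oval` vs
#'   `irregular` body shapes (each summing to 1).
#' @param projection_prob per-subtype probability that an object bears a
#'   tubular projection (orthogonal to the oval/irregular class).
#' @param projection_length_um,projection_tipwidth_um mean and sd (um) of
#'   the projection path length and tip diameter.
#' @param mean_object_volume_nm3 per-subtype mean body volume (nm^3).
#' @param object_volume_cv lognormal coefficient of variation of body
#'   volumes.
#' @param n_nanotunnels number of dumbbell phantoms (two bodies joined by
#'   a thin tube) to place in the interfibrillar space.
#' @param nanotunnel_length_um,nanotunnel_diameter_um uniform ranges (um)
#'   for the tube length and diameter.
#' @param nucleus include a nucleus (required for PNM).
#' @param nucleus_radius_um nucleus semi-axes (um), clamped to fit small
#'   test volumes.
#' @param oval_amplitude,irregular_amplitude radial perturbation
#'   amplitude (relative RMS) of the two body classes.
#' @param myofibril_pitch_um,myofibril_width_um spacing and width of the
#'   unlabelled myofibril slabs separating IFM rows.
#' @param ssm_zone_um depth of the subsarcolemmal zone kept free of
#'   myofibril slabs.
#' @param max_retries rejection-sampling budget per object before a
#'   capacity error is raised.
#' @param seed RNG seed; identical parameters and seed give an identical
#'   volume and ground truth.
#' @return An object of class `volume_params`.
#' @export
volume_params <- function(target_mito_fraction = 0.302,
                          subtype_mix = c(SSM = 0.153, IFM = 0.801,
                                          PNM = 0.047),
                          shape_mix = list(
                            SSM = c(oval = 0.50, irregular = 0.50),
                            IFM = c(oval = 0.69, irregular = 0.31),
                            PNM = c(oval = 0.45, irregular = 0.55)),
                          projection_prob = c(SSM = 0.20, IFM = 0.15,
                                              PNM = 0.30),
                          projection_length_um = c(mean = 0.574,
                                                   sd = 0.415),
                          projection_tipwidth_um = c(mean = 0.220,
                                                     sd = 0.068),
                          mean_object_volume_nm3 = c(SSM = 7.23e8,
                                                     IFM = 7.29e8,
                                                     PNM = 3.70e8),
                          object_volume_cv = 0.25,
                          n_nanotunnels = 0L,
                          nanotunnel_length_um = c(1.1, 1.91),
                          nanotunnel_diameter_um = c(0.28, 0.33),
                          nucleus = TRUE,
                          nucleus_radius_um = c(1.2, 1.2, 0.9),
                          oval_amplitude = 0.04,
                          irregular_amplitude = 0.25,
                          myofibril_pitch_um = 1.5,
                          myofibril_width_um = 0.25,
                          ssm_zone_um = 1.7,
                          max_retries = 100L,
                          seed = 1L) {
  p <- as.list(environment())
  chk_prop <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("`%s` must be proportions in [0, 1]", nm))
  }
  chk_prop(p$target_mito_fraction, "target_mito_fraction")
  chk_prop(p$subtype_mix, "subtype_mix")
  # printed shares may carry rounding (e.g. 15.3 + 80.1 + 4.7 = 100.1);
  # renormalise within a 1 % tolerance
  if (abs(sum(p$subtype_mix) - 1) > 0.01)
    stop("`subtype_mix` must sum to 1")
  p$subtype_mix <- p$subtype_mix / sum(p$subtype_mix)
  if (!identical(sort(names(p$subtype_mix)), c("IFM", "PNM", "SSM")))
    stop("`subtype_mix` must be named SSM, IFM, PNM")
  for (s in names(p$shape_mix)) {
    chk_prop(p$shape_mix[[s]], paste0("shape_mix$", s))
    if (abs(sum(p$shape_mix[[s]]) - 1) > 1e-8)
      stop(sprintf("`shape_mix$%s` must sum to 1", s))
  }
  chk_prop(p$projection_prob, "projection_prob")
  if (p$projection_length_um[["sd"]] < 0 ||
      p$projection_tipwidth_um[["sd"]] < 0)
    stop("distribution sds must be >= 0")
  if (p$n_nanotunnels < 0) stop("`n_nanotunnels` must be >= 0")
  p$n_nanotunnels <- as.integer(p$n_nanotunnels)
  structure(p, class = "volume_params")
}

#' Scale the linear dimensions of generator parameters
#'
#' Multiplies every length parameter by `k` and every volume parameter by
#' `k^3`, matching [scale_geometry()]; used to run the generator on a
#' reduced raster spanning a full-acquisition physical extent.
#'
#' @param params a [volume_params()].
#' @param k positive scale factor.
#' @return A `volume_params`.
#' @export
scale_params <- function(params, k) {
  stopifnot(inherits(params, "volume_params"), k > 0)
  for (nm in c("projection_length_um", "projection_tipwidth_um",
               "nanotunnel_length_um", "nanotunnel_diameter_um",
               "nucleus_radius_um"))
    params[[nm]] <- params[[nm]] * k
  params$myofibril_pitch_um <- params$myofibril_pitch_um * k
  params$myofibril_width_um <- params$myofibril_width_um * k
  params$ssm_zone_um <- params$ssm_zone_um * k
  params$mean_object_volume_nm3 <- params$mean_object_volume_nm3 * k^3
  params
}

# ---------------------------------------------------------------------------
# geometric primitives (all coordinates in nm)

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# low-order directional perturbation with (approximately) unit RMS
random_harmonic <- function() {
  coef <- rnorm(6)
  basis <- function(u) {
    cbind(u[, 1] * u[, 2], u[, 2] * u[, 3], u[, 3] * u[, 1],
          u[, 1]^2 - u[, 2]^2, 3 * u[, 3]^2 - 1,
          u[, 1] * u[, 2] * u[, 3])
  }
  # normalise empirically on a fixed direction sample
  th <- seq(0.05, pi - 0.05, length.out = 24)
  ph <- seq(0, 2 * pi, length.out = 25)[-25]
  dirs <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
                rep(cos(th), length(ph)))
  g <- as.vector(basis(dirs) %*% coef)
  scl <- sqrt(mean(g^2))
  if (scl < 1e-8) scl <- 1
  coef <- coef / scl
  function(u) as.vector(basis(u) %*% coef)
}

# small random rotation (radians sd) about a random axis
wobble_rotation <- function(sd = 0.1) {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- rnorm(1, 0, sd)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# body specification: perturbed ellipsoid (+ optional capsule projection);
# `align = TRUE` orients the longest axis along x and the shortest along
# z (the interfibrillar row geometry), with a small random wobble
make_body_spec <- function(volume_nm3, amplitude, z_cap_nm = Inf,
                           projection = NULL, align = FALSE,
                           z_half_cap_nm = NULL, y_half_cap_nm = NULL) {
  s <- exp(rnorm(3, 0, 0.22))
  s <- s / prod(s)^(1 / 3)
  r0 <- (3 * volume_nm3 / (4 * pi))^(1 / 3) * (1 + 3 * amplitude^2)^(-1 / 3)
  ax <- r0 * s
  # keep bodies from spanning the whole (thin) z extent
  if (2.2 * max(ax) > z_cap_nm) ax <- ax * z_cap_nm / (2.2 * max(ax))
  rot <- if (align) {
    ax <- sort(ax, decreasing = TRUE)
    # flatten into the row band and lane layer, conserving volume by
    # elongation along the row (interfibrillar mitochondria are
    # brick-like between the myofibril sheets); typical-amplitude bound,
    # occasional perturbation outliers are caught by collision checks
    soft <- 1 + 0.8 * amplitude
    if (!is.null(z_half_cap_nm) && ax[3] > 0.95 * z_half_cap_nm / soft) {
      f <- ax[3] / (0.95 * z_half_cap_nm / soft)
      ax[3] <- ax[3] / f
      ax[1] <- ax[1] * f
    }
    if (!is.null(y_half_cap_nm) && ax[2] > 0.95 * y_half_cap_nm / soft) {
      f2 <- ax[2] / (0.95 * y_half_cap_nm / soft)
      ax[2] <- ax[2] / f2
      ax[1] <- ax[1] * f2
    }
    wobble_rotation(0.05)
  } else random_rotation()
  harm <- if (amplitude > 0) random_harmonic() else NULL
  proj <- NULL
  if (!is.null(projection)) {
    w <- rnorm(3)
    w <- w / sqrt(sum(w^2))
    proj <- list(dir = w, length_nm = projection$length_nm,
                 radius_nm = projection$tipwidth_nm / 2)
  }
  list(axes = ax, rot = rot, amp = amplitude, harm = harm, proj = proj)
}

# half-extent of the body (+projection) for box sizing, per axis in nm;
# the support function of a rotated ellipsoid along axis i is
# sqrt(sum_j rot[i,j]^2 axes[j]^2), inflated for the radial perturbation
body_extent_nm <- function(spec) {
  e <- sqrt((spec$rot^2) %*% (spec$axes^2))[, 1] * (1 + 2.05 * spec$amp)
  if (!is.null(spec$proj))
    e <- e + abs(spec$proj$dir) * (spec$proj$length_nm + spec$proj$radius_nm)
  e
}

# evaluate body membership for coordinate rows `d` relative to the centre
body_inside <- function(spec, d) {
  u <- d %*% spec$rot
  m <- sqrt((u[, 1] / spec$axes[1])^2 + (u[, 2] / spec$axes[2])^2 +
            (u[, 3] / spec$axes[3])^2)
  thr <- 1
  if (!is.null(spec$harm)) {
    nrm <- sqrt(rowSums(u^2))
    uh <- u / pmax(nrm, 1e-9)
    thr <- 1 + spec$amp * pmin(spec$harm(uh), 2)
    thr <- pmax(thr, 0.25)
  }
  inside <- m <= thr
  if (!is.null(spec$proj)) {
    # capsule from the body surface outwards along `dir`
    w <- spec$proj$dir
    t_hit <- 1 / sqrt(sum((as.vector(w %*% spec$rot) / spec$axes)^2))
    p1 <- w * (t_hit - spec$proj$radius_nm)       # embedded end
    p2 <- w * (t_hit + spec$proj$length_nm - spec$proj$radius_nm)
    seg <- p2 - p1
    L2 <- sum(seg^2)
    dp <- sweep(d, 2, p1)
    tt <- pmin(pmax((dp %*% seg) / L2, 0), 1)
    dist2 <- rowSums((dp - outer(as.vector(tt), seg))^2)
    inside <- inside | dist2 <= spec$proj$radius_nm^2
  }
  inside
}

# surface area of an ellipsoid (Thomsen approximation, p = 1.6075)
ellipsoid_area <- function(ax) {
  p <- 1.6075
  a <- ax[1]; b <- ax[2]; c <- ax[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# ---------------------------------------------------------------------------

contact_gap_ok <- function(obj, mask, tol_vox = 1) {
  # TRUE when some object voxel lies within a `tol_vox`-voxel gap of the
  # mask (Euclidean distance in voxel-index space <= tol + 1)
  if (!any(mask)) return(FALSE)
  dmask <- dist_to_set(mask, c(1, 1, 1))
  min(dmask[obj]) <= tol_vox + 1 + 1e-9
}

#' Generate a synthetic cardiomyocyte label volume with ground truth
#'
#' Builds a 3-D integer label raster emulating the spatial organisation
#' of cardiac mitochondria: a sarcolemma band along the low-x face with
#' SSM abutting it, a central nucleus with PNM abutting the nuclear
#' envelope, and IFM in rows separated by unlabelled myofibril slabs.
#' Objects are strictly disjoint (rejection sampling) and the realized
#' mitochondrial voxel fraction is driven to the requested target.  The
#' returned ground truth records every object's subtype, shape class,
#' exact voxel volume, analytic surface area where defined, projection
#' and nanotunnel dimensions, and the exact volume-level fractions.
#'
#' @param params a [volume_params()].
#' @param geom a [voxel_geometry()].  The default is a 5.4 x 5.4 x 10 um
#'   cell-scale box on a coarsened raster; pass the acquisition geometry
#'   (13.5 x 13.5 x 50 nm voxels) for full-resolution phantoms of
#'   correspondingly smaller physical extent.
#' @return A list of class `mito_phantom` with elements `volume` (a
#'   [label_volume()]) and `truth` (class `ground_truth`).
#' @examples
#' ph <- simulate_cardiomyocyte(
#'   volume_params(target_mito_fraction = 0.15, nucleus = FALSE, seed = 2),
#'   voxel_geometry(c(96, 96, 20), c(42, 42, 420)))
#' ph$truth$true_fraction
#' @export
simulate_cardiomyocyte <- function(params = volume_params(),
                                   geom = voxel_geometry(c(256, 256, 32),
                                                         c(42, 42, 420))) {
  stopifnot(inherits(params, "volume_params"),
            inherits(geom, "voxel_geometry"))
  set.seed(params$seed)
  d <- geom$dims
  sp <- geom$size_nm
  vox_vol <- prod(sp)

  m0 <- 3L                    # extracellular margin (voxels, x-y faces)
  band <- 2L                  # sarcolemma band thickness (voxels)
  sarc_end <- m0 + band       # innermost sarcolemma voxel index

  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  lim <- d * sp

  # the sarcolemma wraps the cell perimeter in x-y (the z faces are cut
  # faces of the imaged block); extracellular space outside it
  raster <- array(0L, dim = d)
  in_frame <- function(idx, n) idx > m0 & idx <= n - m0
  cell_x <- in_frame(seq_len(d[1]), d[1])
  cell_y <- in_frame(seq_len(d[2]), d[2])
  core_x <- seq_len(d[1]) > sarc_end & seq_len(d[1]) <= d[1] - sarc_end
  core_y <- seq_len(d[2]) > sarc_end & seq_len(d[2]) <= d[2] - sarc_end
  cellxy <- outer(cell_x, cell_y, "&")
  corexy <- outer(core_x, core_y, "&")
  sarc <- array(cellxy & !corexy, dim = d)
  cm <- array(cellxy, dim = d)

  # depth below the sarcolemma inner face, in nm (negative outside)
  depth_x <- pmin(xs - sarc_end * sp[1], (d[1] - sarc_end) * sp[1] - xs)
  depth_y <- pmin(ys - sarc_end * sp[2], (d[2] - sarc_end) * sp[2] - ys)

  # nucleus (analytic ellipsoid, clamped to fit)
  nuc <- NULL
  nuc_c <- NULL
  nuc_r <- NULL
  if (isTRUE(params$nucleus)) {
    nuc_r <- pmin(params$nucleus_radius_um * 1000, 0.30 * lim)
    nuc_c <- c(0.5 * lim[1], 0.5 * lim[2], 0.5 * lim[3])
    fx <- ((xs - nuc_c[1]) / nuc_r[1])^2
    fy <- ((ys - nuc_c[2]) / nuc_r[2])^2
    fz <- ((zs - nuc_c[3]) / nuc_r[3])^2
    nuc <- outer(outer(fx, fy, "+"), fz, "+") <= 1
  }

  # myofibril slabs: stripes along y, only deeper than the SSM zone and
  # clear of the perinuclear shell
  ssm_zone_nm <- params$ssm_zone_um * 1000
  slab_fun <- function(xi, yi, zi) {
    # xi, yi, zi: coordinate vectors (nm) forming a box grid
    iny <- (yi %% (params$myofibril_pitch_um * 1000)) <
      params$myofibril_width_um * 1000
    dxi <- pmin(xi - sarc_end * sp[1], (d[1] - sarc_end) * sp[1] - xi)
    dyi <- pmin(yi - sarc_end * sp[2], (d[2] - sarc_end) * sp[2] - yi)
    deep <- outer(dxi > ssm_zone_nm, dyi > ssm_zone_nm, "&")
    s <- deep & matrix(rep(iny, each = length(xi)), length(xi))
    s <- array(rep(s, length(zi)), dim = c(length(xi), length(yi),
                                           length(zi)))
    if (!is.null(nuc_c)) {
      clear <- nuc_r + 2 * params$myofibril_width_um * 1000
      gx <- ((xi - nuc_c[1]) / clear[1])^2
      gy <- ((yi - nuc_c[2]) / clear[2])^2
      gz <- ((zi - nuc_c[3]) / clear[3])^2
      nearnuc <- outer(outer(gx, gy, "+"), gz, "+") <= 1
      s <- s & !nearnuc
    }
    s
  }

  # interfibrillar lane cursors: IFM pack sequentially along x inside the
  # mitochondrial rows between myofibril slabs, which reaches the in-row
  # packing densities of real myocardium that uniform rejection sampling
  # cannot approach
  pitch_nm <- params$myofibril_pitch_um * 1000
  width_nm <- params$myofibril_width_um * 1000
  band_h <- pitch_nm - width_nm
  typ_ext <- (3 * params$mean_object_volume_nm3[["IFM"]] /
                (4 * pi))^(1 / 3) * 1.25
  row_y <- seq(width_nm + band_h / 2, lim[2], by = pitch_nm)
  row_y <- row_y[row_y > sarc_end * sp[2] + 0.45 * band_h &
                 row_y < lim[2] - sarc_end * sp[2] - 0.45 * band_h]
  if (!length(row_y)) row_y <- lim[2] / 2
  z_lo <- min(0.45 * typ_ext, lim[3] / 2)
  z_hi <- max(lim[3] - 0.45 * typ_ext, lim[3] / 2)
  lane_z_pitch <- 1.15 * typ_ext
  lay_z <- if (z_lo > z_hi) lim[3] / 2 else seq(z_lo, z_hi,
                                                by = lane_z_pitch)
  lanes <- expand.grid(y = row_y, z = lay_z)
  lane_cursor <- rep(sarc_end * sp[1] + 2 * sp[1], nrow(lanes)) +
    runif(nrow(lanes), 0, 0.3 * typ_ext)
  lane_open <- rep(TRUE, nrow(lanes))
  x_stop <- lim[1] - sarc_end * sp[1] - 2 * sp[1]

  # subsarcolemmal face lanes: SSM pack sequentially along y on the two
  # x faces, one z layer per lane
  typ_s <- (3 * params$mean_object_volume_nm3[["SSM"]] /
              (4 * pi))^(1 / 3) * 1.25
  s_lay_z <- if (z_lo > z_hi) lim[3] / 2 else
    seq(min(0.45 * typ_s, lim[3] / 2),
        max(lim[3] - 0.45 * typ_s, lim[3] / 2),
        by = 1.15 * typ_s)
  s_lanes <- expand.grid(face = c("x-", "x+"), z = s_lay_z,
                         stringsAsFactors = FALSE)
  s_cursor <- rep(sarc_end * sp[2] + 2 * sp[2], nrow(s_lanes)) +
    runif(nrow(s_lanes), 0, 0.3 * typ_s)
  s_open <- rep(TRUE, nrow(s_lanes))
  y_stop <- lim[2] - sarc_end * sp[2] - 2 * sp[2]

  cm_vox <- sum(cm)
  tgt_frac <- params$target_mito_fraction
  total_target_vox <- tgt_frac * cm_vox

  truth_obj <- list(); truth_proj <- list(); truth_tun <- list()
  next_label <- 0L

  # -- helpers ---------------------------------------------------------------
  rasterize_at <- function(spec, centre_nm) {
    ext <- body_extent_nm(spec)
    i0 <- floor((centre_nm[1] - ext[1]) / sp[1]) - 1
    i1 <- ceiling((centre_nm[1] + ext[1]) / sp[1]) + 1
    j0 <- floor((centre_nm[2] - ext[2]) / sp[2]) - 1
    j1 <- ceiling((centre_nm[2] + ext[2]) / sp[2]) + 1
    # objects may be clipped at the z faces, which are the cut faces of
    # the imaged block
    k0 <- max(1, floor((centre_nm[3] - ext[3]) / sp[3]) - 1)
    k1 <- min(d[3], ceiling((centre_nm[3] + ext[3]) / sp[3]) + 1)
    if (i0 < 1 || j0 < 1 || i1 > d[1] || j1 > d[2] || k0 > k1)
      return(NULL)
    ii <- i0:i1; jj <- j0:j1; kk <- k0:k1
    cx <- xs[ii]; cy <- ys[jj]; cz <- zs[kk]
    grid <- cbind(rep(cx, times = length(cy) * length(cz)),
                  rep(rep(cy, each = length(cx)), times = length(cz)),
                  rep(cz, each = length(cx) * length(cy)))
    rel <- sweep(grid, 2, centre_nm)
    inside <- body_inside(spec, rel)
    dim(inside) <- c(length(ii), length(jj), length(kk))
    list(mask = inside, ii = ii, jj = jj, kk = kk,
         cx = cx, cy = cy, cz = cz)
  }

  box_free <- function(rb, forbid_extra = NULL) {
    sub_r <- raster[rb$ii, rb$jj, rb$kk, drop = FALSE]
    if (any(sub_r[rb$mask] != 0L)) return(FALSE)
    sub_s <- sarc[rb$ii, rb$jj, rb$kk, drop = FALSE]
    if (any(sub_s[rb$mask])) return(FALSE)
    sub_cm <- cm[rb$ii, rb$jj, rb$kk, drop = FALSE]
    if (any(!sub_cm[rb$mask])) return(FALSE)     # extracellular
    if (!is.null(nuc)) {
      sub_n <- nuc[rb$ii, rb$jj, rb$kk, drop = FALSE]
      if (any(sub_n[rb$mask])) return(FALSE)
    }
    if (!is.null(forbid_extra) && any(forbid_extra[rb$mask])) return(FALSE)
    TRUE
  }

  paint <- function(rb) {
    next_label <<- next_label + 1L
    sub <- raster[rb$ii, rb$jj, rb$kk, drop = FALSE]
    sub[rb$mask] <- next_label
    raster[rb$ii, rb$jj, rb$kk] <<- sub
    next_label
  }

  draw_projection <- function() {
    ln <- max(0.18, rnorm(1, params$projection_length_um[["mean"]],
                          params$projection_length_um[["sd"]])) * 1000
    tw <- max(0.08, rnorm(1, params$projection_tipwidth_um[["mean"]],
                          params$projection_tipwidth_um[["sd"]])) * 1000
    list(length_nm = ln, tipwidth_nm = tw)
  }

  place_one <- function(subtype, vol_nm3, free = FALSE) {
    shp <- sample(c("oval", "irregular"), 1,
                  prob = params$shape_mix[[subtype]])
    amp <- if (shp == "oval") params$oval_amplitude
           else params$irregular_amplitude
    has_proj <- runif(1) < params$projection_prob[[subtype]]
    rejections <- c(fit = 0L, window = 0L, raster = 0L, clip = 0L,
                    slab = 0L, near = 0L, walk = 0L, occupied = 0L)
    lane <- NA_integer_
    slane <- NA_integer_
    bump <- function(step = 0.35) {
      if (identical(subtype, "IFM") && !is.na(lane))
        lane_cursor[lane] <<- lane_cursor[lane] + step * typ_ext
    }
    for (try in seq_len(params$max_retries)) {
      proj <- if (has_proj) draw_projection() else NULL
      spec <- make_body_spec(vol_nm3, amp, z_cap_nm = d[3] * sp[3] * 0.7,
                             projection = proj,
                             align = identical(subtype, "IFM"),
                             z_half_cap_nm = if (identical(subtype, "IFM"))
                               0.5 * lane_z_pitch else NULL,
                             y_half_cap_nm = if (identical(subtype, "IFM"))
                               0.5 * band_h else NULL)
      ext <- body_extent_nm(spec)
      if (any(2 * (ext[1:2] + 2 * sp[1:2]) > lim[1:2])) {
        rejections["fit"] <- rejections["fit"] + 1L; next }
      zc <- runif(1, 0.3 * ext[3], lim[3] - 0.3 * ext[3])
      centre <- NULL
      face <- NULL
      if (identical(subtype, "SSM") && free) {
        face <- sample(c("x-", "x+"), 1L)
        lo2 <- sarc_end * sp[2] + ext[2] + 2 * sp[2]
        hi2 <- lim[2] - sarc_end * sp[2] - ext[2] - 2 * sp[2]
        if (lo2 >= hi2) {
          rejections["window"] <- rejections["window"] + 1L; next }
        centre <- c(if (face == "x-")
          sarc_end * sp[1] + ext[1] + runif(1, 0, 2 * sp[1])
        else lim[1] - sarc_end * sp[1] - ext[1] - runif(1, 0, 2 * sp[1]),
          runif(1, lo2, hi2), zc)
      } else if (identical(subtype, "SSM")) {
        s_ids <- which(s_open)
        if (!length(s_ids))
          stop(errorCondition("sarcolemmal faces full (capacity)",
               class = c("mitomorph_capacity_error", "error",
                         "condition")))
        slane <- if (length(s_ids) == 1L) s_ids else sample(s_ids, 1L)
        face <- s_lanes$face[slane]
        if (s_cursor[slane] + 1.1 * typ_s > y_stop) {
          s_open[slane] <<- FALSE
          rejections["window"] <- rejections["window"] + 1L; next
        }
        if (s_cursor[slane] + 0.6 * ext[2] > y_stop) {
          rejections["window"] <- rejections["window"] + 1L; next
        }
        cy <- min(s_cursor[slane] + ext[2] + sp[2],
                  lim[2] - ext[2] - 2 * sp[2])
        zl <- min(max(s_lanes$z[slane] + runif(1, -0.1, 0.1) * typ_s,
                      0.3 * ext[3]), lim[3] - 0.3 * ext[3])
        centre <- c(if (face == "x-")
          sarc_end * sp[1] + ext[1] + runif(1, 0, 2 * sp[1])
        else lim[1] - sarc_end * sp[1] - ext[1] - runif(1, 0, 2 * sp[1]),
          cy, zl)
      } else if (identical(subtype, "IFM") && free) {
        lo <- sarc_end * sp[1:2] + ext[1:2] + 2 * sp[1:2]
        hi <- lim[1:2] - sarc_end * sp[1:2] - ext[1:2] - 2 * sp[1:2]
        if (any(lo >= hi)) {
          rejections["window"] <- rejections["window"] + 1L; next }
        centre <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), zc)
      } else if (identical(subtype, "IFM")) {
        open_ids <- which(lane_open)
        if (!length(open_ids))
          stop(errorCondition(sprintf(
            "interfibrillar rows full (capacity; cum rejections %s)",
            paste(names(total_rejections), total_rejections, sep = "=",
                  collapse = " ")),
               class = c("mitomorph_capacity_error", "error",
                         "condition")))
        lane <- if (length(open_ids) == 1L) open_ids else
          sample(open_ids, 1L)
        cx <- min(lane_cursor[lane] + ext[1] + sp[1],
                  lim[1] - ext[1] - 2 * sp[1])
        if (lane_cursor[lane] + 1.1 * typ_ext > x_stop) {
          lane_open[lane] <<- FALSE
          rejections["window"] <- rejections["window"] + 1L; next
        }
        if (lane_cursor[lane] + 0.6 * ext[1] > x_stop) {
          # this draw is too long for the remaining row; try again
          rejections["window"] <- rejections["window"] + 1L; next
        }
        zl <- min(max(lanes$z[lane] + runif(1, -0.02, 0.02) * typ_ext,
                      0.3 * ext[3]), lim[3] - 0.3 * ext[3])
        centre <- c(cx, lanes$y[lane] + runif(1, -0.02, 0.02) * band_h,
                    zl)
      } else {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        # start with the body surface just outside the nuclear surface
        t_n <- 1 / sqrt(sum((u / nuc_r)^2))
        t_bu <- 1 / sqrt(sum((as.vector((-u) %*% spec$rot) /
                                spec$axes)^2))
        centre <- nuc_c + u * (t_n + t_bu * (1 + 1.3 * spec$amp) +
                                 2 * min(sp))
      }
      rb <- rasterize_at(spec, centre)
      if (is.null(rb) || !any(rb$mask)) {
        bump()
        rejections["raster"] <- rejections["raster"] + 1L; next }
      shift_box <- function(rb, ax, shift) {
        # translate the box along `ax`, cropping empty padding planes
        dimn <- d[ax]
        idx <- (if (ax == 1L) rb$ii else rb$jj) - shift
        keep <- idx >= 1L & idx <= dimn
        occ <- which(apply(rb$mask, ax, any))
        if (!all(occ %in% which(keep))) return(NULL)  # object clipped
        if (ax == 1L) {
          rb$ii <- idx[keep]
          rb$mask <- rb$mask[keep, , , drop = FALSE]
        } else {
          rb$jj <- idx[keep]
          rb$mask <- rb$mask[, keep, , drop = FALSE]
        }
        rb
      }
      if (identical(subtype, "SSM")) {
        # flush against the sarcolemma band along the face normal
        occ <- which(apply(rb$mask, 1L, any))
        shift <- if (face == "x-") min(rb$ii[occ]) - (sarc_end + 1L)
          else max(rb$ii[occ]) - (d[1] - sarc_end)
        if (shift != 0) {
          rb <- shift_box(rb, 1L, shift)
          if (is.null(rb)) {
            rejections["clip"] <- rejections["clip"] + 1L; next }
        }
        # pack flush against the face-lane cursor along y (lane mode)
        occy <- if (free) integer(0) else which(apply(rb$mask, 2L, any))
        tgt <- if (free) 0L else ceiling(s_cursor[slane] / sp[2]) + 1L
        shifty <- if (free) 0L else min(rb$jj[occy]) - tgt
        if (shifty != 0) {
          rb <- shift_box(rb, 2L, shifty)
          if (is.null(rb)) {
            if (!is.na(slane))
              s_cursor[slane] <<- s_cursor[slane] + 0.35 * typ_s
            rejections["clip"] <- rejections["clip"] + 1L; next }
        }
        if (!free) {
          yocc <- which(apply(rb$mask, 2L, any))
          if (max(rb$jj[yocc]) >= d[2] - sarc_end - 1L) {
            s_open[slane] <<- FALSE
            rejections["window"] <- rejections["window"] + 1L; next
          }
        }
      }
      if (identical(subtype, "IFM") && !free) {
        # pack flush against the lane cursor along x
        occ <- which(apply(rb$mask, 1L, any))
        tgt <- ceiling(lane_cursor[lane] / sp[1]) + 1L
        shift <- min(rb$ii[occ]) - tgt
        if (shift != 0) {
          rb <- shift_box(rb, 1L, shift)
          if (is.null(rb)) {
            bump()
            rejections["clip"] <- rejections["clip"] + 1L; next }
        }
        xocc <- which(apply(rb$mask, 1L, any))
        if (max(rb$ii[xocc]) >= d[1] - sarc_end - 1L) {
          # the row has reached the far sarcolemma
          lane_open[lane] <<- FALSE
          rejections["window"] <- rejections["window"] + 1L; next
        }
      }
      if (identical(subtype, "IFM")) {
        slab <- slab_fun(xs[rb$ii], ys[rb$jj], zs[rb$kk])
        # mitochondria may indent the myofibril faces slightly, but rows
        # must not bridge across a slab
        if (sum(slab[rb$mask]) > 0.08 * sum(rb$mask)) {
          bump()
          rejections["slab"] <- rejections["slab"] + 1L; next }
        # stay clear of both interfaces
        sub_s <- sarc[rb$ii, rb$jj, rb$kk, drop = FALSE]
        if (any(sub_s) &&
            any(dist_to_set(sub_s, c(1, 1, 1))[rb$mask] <= 2.2)) {
          bump()
          rejections["near"] <- rejections["near"] + 1L; next }
        if (!is.null(nuc)) {
          sub_n <- nuc[rb$ii, rb$jj, rb$kk, drop = FALSE]
          if (any(sub_n) &&
              any(dist_to_set(sub_n, c(1, 1, 1))[rb$mask] <= 2.2)) {
            bump()
            rejections["near"] <- rejections["near"] + 1L; next }
        }
      }
      if (identical(subtype, "PNM")) {
        # walk towards the nucleus until the gap closes
        ok <- FALSE
        for (step in 0:24) {
          rb2 <- rasterize_at(spec, centre - u * step * min(sp))
          if (is.null(rb2) || !any(rb2$mask)) break
          sub_n <- nuc[rb2$ii, rb2$jj, rb2$kk, drop = FALSE]
          if (any(sub_n[rb2$mask])) break        # overlapped: give up walk
          if (contact_gap_ok(rb2$mask, sub_n, tol_vox = 1)) {
            rb <- rb2; ok <- TRUE; break
          }
        }
        if (!ok) { rejections["walk"] <- rejections["walk"] + 1L; next }
      }
      if (!box_free(rb)) {
        bump(0.3)
        if (identical(subtype, "SSM") && !is.na(slane))
          s_cursor[slane] <<- s_cursor[slane] + 0.3 * typ_s
        rejections["occupied"] <- rejections["occupied"] + 1L; next }
      if (identical(subtype, "IFM") && !is.na(lane)) {
        xocc <- which(apply(rb$mask, 1L, any))
        lane_cursor[lane] <<- max(rb$ii[xocc]) * sp[1] +
          runif(1, 0, 1) * min(sp[1:2])
      }
      if (identical(subtype, "SSM") && !is.na(slane)) {
        yocc <- which(apply(rb$mask, 2L, any))
        s_cursor[slane] <<- max(rb$jj[yocc]) * sp[2] +
          runif(1, 0, 1) * min(sp[1:2])
      }
      lab <- paint(rb)
      n_vox <- sum(rb$mask)
      sa <- if (shp == "oval" && is.null(spec$proj))
        ellipsoid_area(spec$axes) else NA_real_
      truth_obj[[length(truth_obj) + 1L]] <<- data.frame(
        label = lab, subtype = subtype, shape_class = shp,
        has_projection = has_proj, n_vox = n_vox,
        volume_nm3 = n_vox * vox_vol, surface_area_nm2 = sa,
        nanotunnel = FALSE)
      if (has_proj)
        truth_proj[[length(truth_proj) + 1L]] <<- data.frame(
          label = lab, length_um = spec$proj$length_nm / 1000,
          tip_width_um = 2 * spec$proj$radius_nm / 1000)
      total_rejections <<- total_rejections + rejections
      return(n_vox)
    }
    total_rejections <<- total_rejections + rejections
    stop(errorCondition(
      sprintf("could not place %s object after %d retries (capacity; %s)",
              subtype, params$max_retries,
              paste(names(rejections), rejections, sep = "=",
                    collapse = " ")),
      class = c("mitomorph_capacity_error", "error", "condition")))
  }

  place_nanotunnel <- function(vol_nm3) {
    tun_len <- runif(1, params$nanotunnel_length_um[1],
                     params$nanotunnel_length_um[2]) * 1000
    tun_r <- runif(1, params$nanotunnel_diameter_um[1],
                   params$nanotunnel_diameter_um[2]) * 500
    for (try in seq_len(params$max_retries)) {
      w <- c(rnorm(2), rnorm(1) * 0.15)      # keep tube near-in-plane
      w <- w / sqrt(sum(w^2))
      s1 <- make_body_spec(vol_nm3 / 2, params$oval_amplitude,
                           z_cap_nm = d[3] * sp[3] * 0.8)
      s2 <- make_body_spec(vol_nm3 / 2, params$oval_amplitude,
                           z_cap_nm = d[3] * sp[3] * 0.8)
      t1 <- 1 / sqrt(sum((as.vector(w %*% s1$rot) / s1$axes)^2))
      t2 <- 1 / sqrt(sum((as.vector((-w) %*% s2$rot) / s2$axes)^2))
      sep <- t1 + tun_len + t2
      e1 <- body_extent_nm(s1); e2 <- body_extent_nm(s2)
      ext <- pmax(e1, e2) + abs(w) * sep
      lo1 <- sarc_end * sp[1] + ext[1] + 4 * sp[1]
      hi1 <- lim[1] - sarc_end * sp[1] - ext[1] - 4 * sp[1]
      lo2 <- sarc_end * sp[2] + ext[2] + 4 * sp[2]
      hi2 <- lim[2] - sarc_end * sp[2] - ext[2] - 4 * sp[2]
      lo3 <- ext[3] + sp[3]
      hi3 <- lim[3] - ext[3] - sp[3]
      if (lo1 >= hi1 || lo2 >= hi2 || lo3 >= hi3) next
      c1 <- c(runif(1, lo1, hi1), runif(1, lo2, hi2), runif(1, lo3, hi3))
      c2 <- c1 + w * sep
      rb1 <- rasterize_at(s1, c1)
      rb2 <- rasterize_at(s2, c2)
      if (is.null(rb1) || is.null(rb2)) next
      # tube capsule between body surfaces
      p1 <- c1 + w * (t1 - tun_r)
      p2 <- c1 + w * (t1 + tun_len + tun_r)
      ii <- min(rb1$ii, rb2$ii):max(rb1$ii, rb2$ii)
      jj <- min(rb1$jj, rb2$jj):max(rb1$jj, rb2$jj)
      kk <- min(rb1$kk, rb2$kk):max(rb1$kk, rb2$kk)
      grid <- cbind(rep(xs[ii], times = length(jj) * length(kk)),
                    rep(rep(ys[jj], each = length(ii)), times = length(kk)),
                    rep(zs[kk], each = length(ii) * length(jj)))
      seg <- p2 - p1
      dp <- sweep(grid, 2, p1)
      tt <- pmin(pmax((dp %*% seg) / sum(seg^2), 0), 1)
      tube <- rowSums((dp - outer(as.vector(tt), seg))^2) <= tun_r^2
      m <- array(FALSE, dim = c(length(ii), length(jj), length(kk)))
      m[tube] <- TRUE
      rb <- list(mask = m, ii = ii, jj = jj, kk = kk)
      # merge body masks into the common box
      off1 <- c(match(rb1$ii[1], ii), match(rb1$jj[1], jj),
                match(rb1$kk[1], kk))
      rb$mask[off1[1]:(off1[1] + dim(rb1$mask)[1] - 1),
              off1[2]:(off1[2] + dim(rb1$mask)[2] - 1),
              off1[3]:(off1[3] + dim(rb1$mask)[3] - 1)] <-
        rb$mask[off1[1]:(off1[1] + dim(rb1$mask)[1] - 1),
                off1[2]:(off1[2] + dim(rb1$mask)[2] - 1),
                off1[3]:(off1[3] + dim(rb1$mask)[3] - 1)] | rb1$mask
      off2 <- c(match(rb2$ii[1], ii), match(rb2$jj[1], jj),
                match(rb2$kk[1], kk))
      rb$mask[off2[1]:(off2[1] + dim(rb2$mask)[1] - 1),
              off2[2]:(off2[2] + dim(rb2$mask)[2] - 1),
              off2[3]:(off2[3] + dim(rb2$mask)[3] - 1)] <-
        rb$mask[off2[1]:(off2[1] + dim(rb2$mask)[1] - 1),
                off2[2]:(off2[2] + dim(rb2$mask)[2] - 1),
                off2[3]:(off2[3] + dim(rb2$mask)[3] - 1)] | rb2$mask
      if (min(rb$ii) <= sarc_end + 3L) next
      if (!box_free(rb)) next
      lab <- paint(rb)
      n_vox <- sum(rb$mask)
      truth_obj[[length(truth_obj) + 1L]] <<- data.frame(
        label = lab, subtype = "IFM", shape_class = "oval",
        has_projection = FALSE, n_vox = n_vox,
        volume_nm3 = n_vox * vox_vol, surface_area_nm2 = NA_real_,
        nanotunnel = TRUE)
      truth_tun[[length(truth_tun) + 1L]] <<- data.frame(
        label = lab, length_um = tun_len / 1000,
        diameter_um = 2 * tun_r / 1000)
      return(n_vox)
    }
    stop(errorCondition(
      sprintf("could not place nanotunnel after %d retries (capacity)",
              params$max_retries),
      class = c("mitomorph_capacity_error", "error", "condition")))
  }

  # -- placement loop --------------------------------------------------------
  placed_vox <- 0
  if (params$n_nanotunnels > 0) {
    for (q in seq_len(params$n_nanotunnels))
      placed_vox <- placed_vox +
        place_nanotunnel(1.4 * params$mean_object_volume_nm3[["IFM"]])
  }
  total_rejections <- c(fit = 0L, window = 0L, raster = 0L, clip = 0L,
                        slab = 0L, near = 0L, walk = 0L, occupied = 0L)
  overflow_to_ifm <- 0
  if (tgt_frac > 0) {
    for (subtype in c("PNM", "SSM", "IFM")) {
      share <- params$subtype_mix[[subtype]]
      if (share <= 0) next
      if (subtype == "PNM" && is.null(nuc))
        stop("PNM requested but `nucleus = FALSE`")
      mean_v <- params$mean_object_volume_nm3[[subtype]]
      mean_vox <- mean_v / vox_vol
      target_vox <- total_target_vox * share
      if (subtype == "IFM")
        target_vox <- target_vox - placed_vox + overflow_to_ifm
      cum <- 0
      lanes_jammed <- FALSE
      gap_fail <- 0L
      gap_scale <- 0.45
      sdlog <- sqrt(log(1 + params$object_volume_cv^2))
      meanlog <- log(mean_v) - sdlog^2 / 2
      n_guard <- 0
      while (target_vox - cum > 0.15 * mean_vox) {
        n_guard <- n_guard + 1
        if (n_guard > 60 * (1 + target_vox / mean_vox))
          stop(errorCondition("object budget exhausted (capacity)",
               class = c("mitomorph_capacity_error", "error", "condition")))
        v <- rlnorm(1, meanlog, sdlog)
        rem_nm3 <- (target_vox - cum) * vox_vol
        if (v > 1.25 * rem_nm3) v <- max(rem_nm3, 0.2 * mean_v)
        gap_mode <- FALSE
        placed <- if (subtype == "PNM") {
          # the nuclear envelope has finite packing capacity; once it
          # jams, the remaining perinuclear budget becomes interfibrillar
          tryCatch(place_one(subtype, v),
                   mitomorph_capacity_error = function(e) NA_real_)
        } else if (!lanes_jammed) {
          tryCatch(place_one(subtype, v),
                   mitomorph_capacity_error = function(e) {
                     lanes_jammed <<- TRUE
                     NA_real_
                   })
        } else {
          # lanes are jammed: squeeze smaller mitochondria into the
          # remaining interstices, as densely packed myocardium does
          gap_mode <- TRUE
          tryCatch(place_one(subtype, min(v, gap_scale * mean_v),
                             free = TRUE),
                   mitomorph_capacity_error = function(e) NA_real_)
        }
        if (is.na(placed)) {
          if (subtype == "PNM") {
            overflow_to_ifm <- overflow_to_ifm + target_vox - cum
            break
          }
          if (gap_mode) {
            gap_fail <- gap_fail + 1L
            gap_scale <- max(0.15, gap_scale * 0.8)
            if (gap_fail > 30L) {
              if (subtype == "SSM") {
                # the sarcolemmal shell is saturated; the rest of the
                # budget becomes interfibrillar
                overflow_to_ifm <- overflow_to_ifm + target_vox - cum
                break
              }
              stop(errorCondition(
                sprintf(
                  "gap filling exhausted [IFM: placed %.0f of %.0f target voxels]",
                  cum, target_vox),
                class = c("mitomorph_capacity_error", "error",
                          "condition")))
            }
          }
          next
        }
        if (gap_mode) gap_fail <- 0L
        cum <- cum + placed
      }
    }
  }

  vol <- label_volume(raster, geom, nucleus_mask = nuc,
                      sarcolemma_mask = sarc, cm_mask = cm)
  objs <- if (length(truth_obj)) do.call(rbind, truth_obj) else
    data.frame(label = integer(0), subtype = character(0),
               shape_class = character(0), has_projection = logical(0),
               n_vox = integer(0), volume_nm3 = numeric(0),
               surface_area_nm2 = numeric(0), nanotunnel = logical(0))
  mito_vox <- sum(objs$n_vox)
  shares <- vapply(c("SSM", "IFM", "PNM"), function(s)
    sum(objs$n_vox[objs$subtype == s]) / max(mito_vox, 1L), numeric(1))
  truth <- structure(list(
    objects = objs,
    projections = if (length(truth_proj)) do.call(rbind, truth_proj) else
      data.frame(label = integer(0), length_um = numeric(0),
                 tip_width_um = numeric(0)),
    nanotunnels = if (length(truth_tun)) do.call(rbind, truth_tun) else
      data.frame(label = integer(0), length_um = numeric(0),
                 diameter_um = numeric(0)),
    true_fraction = mito_vox / cm_vox,
    subtype_share = shares,
    mito_vox = mito_vox, cm_vox = cm_vox,
    params = unclass(params)), class = "ground_truth")
  structure(list(volume = vol, truth = truth), class = "mito_phantom")
}

#' @export
print.mito_phantom <- function(x, ...) {
  cat(sprintf("mito_phantom: %d objects, true mito fraction %.3f\n",
              nrow(x$truth$objects), x$truth$true_fraction))
  print(x$volume)
  invisible(x)
}

#' Rasterize a single synthetic mitochondrion
#'
#' Generates one body (plus optional tubular projection) in its own small
#' label volume, mainly for estimator-validation experiments where the
#' cardiomyocyte context is not needed.
#'
#' @param volume_nm3 target body volume.
#' @param shape_class `"oval"` or `"irregular"`.
#' @param amplitude radial perturbation amplitude; defaults to the
#'   generator defaults for the class.
#' @param projection `NULL`, or a list with `length_um` and
#'   `tipwidth_um`.
#' @param geom_size_nm voxel size (nm).
#' @param seed optional RNG seed.
#' @return A list with `volume` (a [label_volume()] containing one label)
#'   and `truth` (one-row data frame).
#' @export
simulate_mitochondrion <- function(volume_nm3 = 7.29e8,
                                   shape_class = c("oval", "irregular"),
                                   amplitude = NULL,
                                   projection = NULL,
                                   geom_size_nm = c(13.5, 13.5, 50),
                                   seed = NULL) {
  shape_class <- match.arg(shape_class)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitude))
    amplitude <- if (shape_class == "oval") 0.04 else 0.25
  proj <- if (!is.null(projection))
    list(length_nm = projection$length_um * 1000,
         tipwidth_nm = projection$tipwidth_um * 1000)
  spec <- make_body_spec(volume_nm3, amplitude, projection = proj)
  ext <- body_extent_nm(spec)
  dims <- pmax(ceiling(2 * (ext + 3 * geom_size_nm) / geom_size_nm), 8)
  geom <- voxel_geometry(dims, geom_size_nm)
  centre <- dims * geom_size_nm / 2
  xi <- (seq_len(dims[1]) - 0.5) * geom_size_nm[1]
  yi <- (seq_len(dims[2]) - 0.5) * geom_size_nm[2]
  zi <- (seq_len(dims[3]) - 0.5) * geom_size_nm[3]
  grid <- cbind(rep(xi, times = dims[2] * dims[3]),
                rep(rep(yi, each = dims[1]), times = dims[3]),
                rep(zi, each = dims[1] * dims[2]))
  inside <- body_inside(spec, sweep(grid, 2, centre))
  raster <- array(0L, dim = dims)
  raster[inside] <- 1L
  truth <- data.frame(
    label = 1L, shape_class = shape_class,
    has_projection = !is.null(projection),
    n_vox = sum(inside), volume_nm3 = sum(inside) * prod(geom_size_nm),
    surface_area_nm2 = if (shape_class == "oval" && is.null(projection))
      ellipsoid_area(spec$axes) else NA_real_,
    proj_length_um = if (!is.null(projection)) projection$length_um
      else NA_real_,
    proj_tipwidth_um = if (!is.null(projection)) projection$tipwidth_um
      else NA_real_)
  list(volume = label_volume(raster, geom), truth = truth)
}
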