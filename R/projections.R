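# Tubular projection and nanotunnel detection on label volumes.
#
# Both detectors work on the anisotropy-aware Euclidean distance
# transform of the object.  The "body" of an object is recovered by a
# morphological opening (erosion threshold on the EDT followed by a
# metric dilation); thin appendages that the opening removes are the
# projection candidates.  Lengths are geodesic path lengths over the
# voxel adjacency graph in physical (nm) coordinates, never voxel steps,
# and local widths are read off the distance transform, so all outputs
# respect the anisotropic voxel geometry.

#' Detect tubular projections of a mitochondrion
#'
#' A projection is a thin terminal appendage: a connected region removed
#' by the morphological opening of the object, attached to the body,
#' whose centreline path length is at least `min_length_um` and whose
#' local diameter does not exceed `frac_body` times the body equivalent
#' diameter.  The path length is the geodesic distance (nm-weighted)
#' from the attachment to the free tip; the tip width is twice the
#' distance-transform value at the path node `tip_offset` steps from the
#' free end, honouring measurement close to the furthermost tip.
#'
#' @param volume a [label_volume()].
#' @param label label id.
#' @param min_length_um minimum projection path length (um).
#' @param frac_body maximum local diameter as a fraction of the body
#'   equivalent diameter.
#' @param tip_offset number of path nodes from the free end at which the
#'   tip width is read.
#' @return A data frame with one row per projection: `length_um`,
#'   `tip_width_um`, `attach_i/j/k` (voxel index of the attachment).
#' @export
detect_projections <- function(volume, label, min_length_um = 0.25,
                               frac_body = 0.5, tip_offset = 3L) {
  box <- get_label_box(volume, label)
  sp <- volume$geom$size_nm
  cb <- crop_box(volume, box, pad = 2L)
  obj <- cb$raster == box$label
  empty <- data.frame(length_um = numeric(0), tip_width_um = numeric(0),
                      attach_i = integer(0), attach_j = integer(0),
                      attach_k = integer(0))
  v_nm3 <- sum(obj) * prod(sp)
  d_eq <- 2 * (3 * v_nm3 / (4 * pi))^(1 / 3)
  edt <- edt_inside(obj, sp)
  body <- open_body(obj, sp)
  app <- obj & !body
  if (!any(app)) return(empty)
  lab <- label_components(app, 26L)
  near_body <- dist_to_set(body, c(1, 1, 1)) <= sqrt(3) + 1e-9
  out <- list()
  for (cid in seq_len(max(lab))) {
    comp <- lab == cid
    n <- sum(comp)
    if (n < 4L) next
    att <- comp & near_body
    if (!any(att)) next
    vg <- voxel_graph(comp, sp)
    att_ids <- vg$id[att]
    dists <- igraph::distances(vg$graph, v = att_ids)
    dmin <- apply(dists, 2, min)
    tip <- which.max(dmin)
    len_nm <- dmin[tip]
    if (!is.finite(len_nm) || len_nm < min_length_um * 1000) next
    src <- att_ids[which.min(dists[, tip])]
    pth <- igraph::shortest_paths(vg$graph, from = src, to = tip,
                                  output = "vpath")$vpath[[1]]
    pth <- as.integer(pth)
    edt_v <- edt[comp]                      # indexed by vg vertex id
    # local diameter along the path, away from the body junction
    mid <- pth[max(1, floor(length(pth) * 0.3)):length(pth)]
    local_diam <- 2 * median(edt_v[mid])
    if (local_diam > frac_body * d_eq) next
    # width close to the furthermost tip: within the rounded tip cap the
    # distance transform falls towards zero, so the local calibre is the
    # thickest point in a neighbourhood just behind the free end (at
    # least `tip_offset` voxels, capped at a fraction of the length)
    co_comp <- mask_coords(comp)
    tip_co <- co_comp[tip, ]
    dtip <- sqrt(((co_comp[, 1] - tip_co[1]) * sp[1])^2 +
                 ((co_comp[, 2] - tip_co[2]) * sp[2])^2 +
                 ((co_comp[, 3] - tip_co[3]) * sp[3])^2)
    reach <- max(tip_offset * min(sp), min(300, 0.45 * len_nm))
    tipw_nm <- 2 * max(edt_v[dtip <= reach])
    att_co <- mask_coords(att)
    a <- att_co[which.min(dists[, tip]), ]
    out[[length(out) + 1L]] <- data.frame(
      length_um = len_nm / 1000, tip_width_um = tipw_nm / 1000,
      attach_i = a[1] + cb$origin[1] - 1L,
      attach_j = a[2] + cb$origin[2] - 1L,
      attach_k = a[3] + cb$origin[3] - 1L)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Detect nanotunnels in a label volume
#'
#' A nanotunnel is a thin tubular bridge joining two mitochondrial
#' bodies.  Within each labelled object the detector finds the interior
#' "cores" (distance-transform peaks thicker than the maximum tunnel
#' radius); when two or more cores exist, the two largest are
#' reconstructed by metric dilation (a morphological opening that strips
#' anything thinner than `max_tunnel_diam_um`), and the remaining tube
#' region connecting them is measured: the tube length is the shortest
#' geodesic between the two body surfaces through the tube, the diameter
#' twice the deepest distance-transform value inside it.  A tunnel is
#' reported when it is at least `min_tunnel_length_um` long and both
#' bodies are thicker than twice the tube diameter.
#'
#' @param volume a [label_volume()].
#' @param min_tunnel_length_um minimum tube length (um).
#' @param max_tunnel_diam_um maximum tube diameter (um).
#' @return A data frame with one row per nanotunnel: `label`,
#'   `tube_length_um`, `tube_diameter_um`.
#' @export
detect_nanotunnels <- function(volume, min_tunnel_length_um = 1.0,
                               max_tunnel_diam_um = 0.4) {
  sp <- volume$geom$size_nm
  r_max <- max_tunnel_diam_um * 1000 / 2
  info <- label_info(volume)
  empty <- data.frame(label = integer(0), tube_length_um = numeric(0),
                      tube_diameter_um = numeric(0))
  out <- list()
  for (r in seq_len(nrow(info))) {
    box <- info[r, ]
    # a dumbbell must span at least the minimum tunnel length
    span_nm <- sqrt(((box$i1 - box$i0) * sp[1])^2 +
                    ((box$j1 - box$j0) * sp[2])^2 +
                    ((box$k1 - box$k0) * sp[3])^2)
    if (span_nm < min_tunnel_length_um * 1000) next
    cb <- crop_box(volume, box, pad = 2L)
    obj <- cb$raster == box$label
    edt <- edt_inside(obj, sp)
    core <- edt > r_max * 1.05
    if (!any(core)) next
    clab <- label_components(core, 26L)
    nc <- max(clab)
    if (nc < 2L) next
    sizes <- tabulate(clab[clab > 0L], nbins = nc)
    big2 <- order(sizes, decreasing = TRUE)[1:2]
    # both bodies must be substantial: inradius at least the tube radius
    inrad <- vapply(big2, function(b) max(edt[clab == b]), numeric(1))
    # reconstruct the two bodies by metric dilation of their cores (the
    # morphological opening that removes the tube), then measure the
    # geodesic through the remaining tube region between them
    b1 <- obj & dist_to_set(clab == big2[1], sp) <= r_max * 1.05 + 0.2 * min(sp)
    b2 <- obj & dist_to_set(clab == big2[2], sp) <= r_max * 1.05 + 0.2 * min(sp)
    tube_reg <- obj & !b1 & !b2
    if (!any(tube_reg)) next
    near1 <- dist_to_set(b1, c(1, 1, 1)) <= sqrt(3) + 1e-9
    near2 <- dist_to_set(b2, c(1, 1, 1)) <= sqrt(3) + 1e-9
    tlab <- label_components(tube_reg, 26L)
    found <- FALSE
    for (tc in seq_len(max(tlab))) {
      comp <- tlab == tc
      a1 <- comp & near1
      a2 <- comp & near2
      if (!any(a1) || !any(a2)) next
      vg <- voxel_graph(comp, sp)
      dmat <- igraph::distances(vg$graph, v = vg$id[a1])
      dmin <- suppressWarnings(apply(dmat[, vg$id[a2], drop = FALSE], 2,
                                     min))
      if (!any(is.finite(dmin))) next
      best_len <- min(dmin)
      # the centreline calibre: the deepest interior point of the tube
      tube_diam <- 2 * max(edt[comp])
      found <- TRUE
      break
    }
    if (!found) next
    if (best_len < min_tunnel_length_um * 1000) next
    if (any(2 * inrad < 2 * tube_diam)) next
    out[[length(out) + 1L]] <- data.frame(
      label = box$label, tube_length_um = best_len / 1000,
      tube_diameter_um = tube_diam / 1000)
  }
  if (length(out)) do.call(rbind, out) else empty
}
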