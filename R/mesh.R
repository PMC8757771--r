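#' Build the 2-D cross-section mesh of a wood-pile scaffold unit cell
#'
#' The cross-section alternates, layer by layer, between strands running in
#' the section plane (seen as full-width rectangles) and strands running out
#' of plane (seen as rectangular cross-sections of width `strand_width`,
#' spaced centre-to-centre by `inter_fiber_distance`). One spacing period is
#' meshed, with half an out-of-plane strand at each lateral (symmetry) edge.
#' Odd layers are in-plane, even layers out-of-plane, counted from the build
#' plate. With `with_support = TRUE` the voids are filled with elements
#' labelled `support` (embedded / bioplotting strategy); otherwise they stay
#' empty.
#'
#' @param cell A [scaffold_cell].
#' @param with_support Fill the pores with a sacrificial support bath?
#' @param target_element_size Nominal element edge length, m. The default
#'   yields a mesh of order 500-1000 linear triangles.
#' @return An object of class `mesh2d`: list with `nodes` (n x 2 matrix, m),
#'   `triangles` (m x 3 index matrix, counter-clockwise), `label` (per-element
#'   factor, `gel` / `support`), boundary node-index vectors `bottom`, `left`,
#'   `right`, `top`, the monitored node `point_a`, the structure `height` and
#'   the slab `thickness` (out-of-plane, m).
#' @examples
#' m <- build_unit_cell_mesh(scaffold_cell(), with_support = FALSE)
#' nrow(m$triangles)
#' @export
build_unit_cell_mesh <- function(cell, with_support = FALSE,
                                 target_element_size = 1.4e-4) {
  stopifnot(inherits(cell, "scaffold_cell"), target_element_size > 0)
  w <- cell$strand_width
  lh <- cell$layer_height
  W <- cell$inter_fiber_distance
  nl <- cell$n_layers
  H <- nl * lh

  seg_breaks <- function(a, b, size) {
    k <- max(1L, ceiling((b - a) / size))
    seq(a, b, length.out = k + 1L)
  }
  # x grid honours the strand edges at w/2 and W - w/2
  xb <- unique(c(seg_breaks(0, w / 2, target_element_size),
                 seg_breaks(w / 2, W - w / 2, target_element_size),
                 seg_breaks(W - w / 2, W, target_element_size)))
  # z grid honours every layer interface
  zb <- unique(unlist(lapply(seq_len(nl), function(i) {
    seg_breaks((i - 1) * lh, i * lh, target_element_size)
  })))
  nx <- length(xb) - 1L
  nz <- length(zb) - 1L

  node_id <- matrix(seq_len((nx + 1L) * (nz + 1L)), nrow = nx + 1L)
  nodes <- cbind(rep(xb, times = nz + 1L), rep(zb, each = nx + 1L))

  in_gel <- function(xc, zc) {
    layer <- pmin(nl, floor(zc / lh) + 1L)
    in_plane <- layer %% 2L == 1L
    in_strand <- xc <= w / 2 | xc >= W - w / 2
    in_plane | in_strand
  }

  tris <- vector("list", 2L * nx * nz)
  labs <- character(2L * nx * nz)
  k <- 0L
  for (j in seq_len(nz)) {
    zc <- (zb[j] + zb[j + 1L]) / 2
    for (i in seq_len(nx)) {
      xc <- (xb[i] + xb[i + 1L]) / 2
      gel_cell <- in_gel(xc, zc)
      if (!gel_cell && !with_support) next
      lab <- if (gel_cell) "gel" else "support"
      n00 <- node_id[i, j]; n10 <- node_id[i + 1L, j]
      n01 <- node_id[i, j + 1L]; n11 <- node_id[i + 1L, j + 1L]
      k <- k + 1L; tris[[k]] <- c(n00, n10, n11); labs[k] <- lab
      k <- k + 1L; tris[[k]] <- c(n00, n11, n01); labs[k] <- lab
    }
  }
  tri <- do.call(rbind, tris[seq_len(k)])
  labs <- labs[seq_len(k)]

  # drop unused grid nodes (void regions of the no-support mesh)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3L)

  tol <- 1e-9 * max(W, H)
  bottom <- which(abs(nodes[, 2]) < tol)
  left <- which(abs(nodes[, 1]) < tol)
  right <- which(abs(nodes[, 1] - W) < tol)
  top <- which(abs(nodes[, 2] - H) < tol)

  # monitored point A: upper outer corner of the top strand when the top layer
  # is out-of-plane; mid-span of the top slab otherwise (maximum sag point)
  target_x <- if (nl %% 2L == 0L) w / 2 else W / 2
  cand <- top[which.min(abs(nodes[top, 1] - target_x))]

  structure(list(nodes = nodes, triangles = tri,
                 label = factor(labs, levels = c("gel", "support")),
                 bottom = bottom, left = left, right = right, top = top,
                 point_a = cand, height = H,
                 thickness = cell$out_of_plane_thickness,
                 cell = cell, with_support = with_support),
            class = "mesh2d")
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("2D mesh: %d nodes, %d triangles (%d gel, %d support)\n",
              nrow(x$nodes), nrow(x$triangles),
              sum(x$label == "gel"), sum(x$label == "support")))
  cat(sprintf("  extent %.3g x %.3g mm; point A at (%.3g, %.3g) mm\n",
              1e3 * max(x$nodes[, 1]), 1e3 * max(x$nodes[, 2]),
              1e3 * x$nodes[x$point_a, 1], 1e3 * x$nodes[x$point_a, 2]))
  invisible(x)
}

# signed triangle areas; positive for counter-clockwise connectivity
triangle_areas <- function(mesh) {
  p <- mesh$nodes
  t <- mesh$triangles
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Export a mesh as Gmsh 2.2 ASCII
#'
#' Plain-text unstructured-mesh exchange format readable by Gmsh, meshio and
#' most FE pre/post-processors. Subdomain labels are written as physical tags
#' (1 = gel, 2 = support).
#'
#' @param mesh A [mesh2d][build_unit_cell_mesh()].
#' @param path Output file path (conventionally `.msh`).
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$triangles))), con)
  tag <- as.integer(mesh$label)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nrow(mesh$triangles)),
                     tag, tag, mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
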