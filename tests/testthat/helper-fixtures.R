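fx <- f9_fixtures()

# flow rate through the reference system at the standard piston speed
ref_flow_rate <- function(piston_radius = 6e-3, inlet_velocity = 1e-5) {
  inlet_velocity * pi * piston_radius^2
}

# hand-built unit-square mesh (side a, two triangles) for lumped-limit tests
single_square_mesh <- function(a = 1e-3, thickness = 1e-3) {
  nodes <- rbind(c(0, 0), c(a, 0), c(a, a), c(0, a))
  structure(list(
    nodes = nodes,
    triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    label = factor(c("gel", "gel"), levels = c("gel", "support")),
    bottom = c(1L, 2L), left = c(1L, 4L), right = c(2L, 3L),
    top = c(3L, 4L), point_a = 4L, height = a, thickness = thickness,
    cell = NULL, with_support = FALSE), class = "mesh2d")
}

# solid rectangular column (single full-width layer) as a scaffold cell
column_cell <- function(H = 3.3e-3, W = 4e-3) {
  scaffold_cell(strand_width = W * 0.85, layer_height = H,
                inter_fiber_distance = W, n_layers = 1L)
}
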