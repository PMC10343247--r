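# Shared fixtures: constituent materials and small meshes built in code.

kevlar <- function() trans_iso_material(E11 = 128700, E22 = 12870, v12 = 0.3,
                                        v23 = -0.5, G12 = 12870, G23 = 12870,
                                        name = "Kevlar")
pcu <- function() isotropic_material(E = 57, v = 0.43, name = "PCU")

unit_cube <- function() box_mesh(0:1, 0:1, 0:1)

cube_coords <- function() {
  m <- unit_cube()
  m$nodes[m$elements[1, ], , drop = FALSE]
}

# A 2x2x2-element cube with its interior node displaced (distorted but valid).
distorted_cube_mesh <- function() {
  m <- box_mesh(seq(0, 2, 1), seq(0, 2, 1), seq(0, 2, 1))
  interior <- which(apply(m$nodes, 1, function(p) all(p > 0.5 & p < 1.5)))
  m$nodes[interior, ] <- m$nodes[interior, ] + c(0.17, -0.11, 0.13)
  hex_mesh(m$nodes, m$elements)
}

# Energy of a displacement field over element stiffness k.
quad_energy <- function(k, u) as.numeric(u %*% (k %*% u))

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
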