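# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the reference SRS-like synthetic plan: 3 cm spherical target, 15 Gy at its
# surface, inverse-square fall-off, 125% hot core, 40 mm body
fix_radial_plan <- function() {
  memo("radial_plan",
       make_radial_dose(target_radius = 15, reference_dose = 15,
                        falloff_exponent = 2, core_max_pct = 125,
                        grid_spacing = 1, body_radius = 40))
}

fix_radial_fit <- function() {
  p <- fix_radial_plan()
  memo("radial_fit", dgc(p$dose, prescription = 15, body = p$body,
                         ptv = p$ptv, step = 1))
}

# a compact plan for I/O and smoke tests
fix_small_plan <- function() {
  memo("small_plan",
       make_radial_dose(target_radius = 7.5, reference_dose = 18,
                        falloff_exponent = 2, core_max_pct = 120,
                        grid_spacing = 1, body_radius = 22))
}

# axis-aligned cube as 12 outward-oriented triangles
cube_mesh <- function(edge = 1, center = c(0, 0, 0)) {
  h <- edge / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, -center)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m <- triangle_mesh(v, f[, c(1, 3, 2)])
  m
}

# subdivided icosahedron projected to a sphere: inscribed polyhedron whose
# area/volume converge to the sphere's from below
icosphere <- function(radius = 1, subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      V <<- rbind(V, (V[a, ] + V[b, ]) / 2)
      mid[[key]] <- nrow(V)
      nrow(V)
    }
    F2 <- matrix(0L, 0, 3)
    for (q in seq_len(nrow(F))) {
      a <- F[q, 1]; b <- F[q, 2]; c <- F[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      F2 <- rbind(F2, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    F <- F2
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  m <- triangle_mesh(V, F)
  if (mesh_volume(m) < 0) m <- triangle_mesh(V, F[, c(1, 3, 2)])
  m
}

# Table-style fixture tables bundled with the package
layer_table <- function() example_multilayer_table()
srs_table <- function() example_srs_table()

# wrap a data frame as a dgc_table with the attributes the curve math needs
as_dgc_table <- function(df, step = 1, dose_scale = "percent",
                         reference_dose = NULL) {
  structure(df, step = step, dose_scale = dose_scale,
            reference_dose = reference_dose,
            class = c("dgc_table", "data.frame"))
}
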