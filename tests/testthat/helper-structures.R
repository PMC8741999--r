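# build a structure_model from compact per-atom rows:
# list(c(name, resname, chain, resseq, x, y, z), ...)
make_structure <- function(rows, id = "toy") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(atom_name = r[[1]], resname = r[[2]], chain = r[[3]],
               resseq = as.integer(r[[4]]), x = as.numeric(r[[5]]),
               y = as.numeric(r[[6]]), z = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)
  }))
  structure_model(df, id = id)
}

# apply a rigid motion (rotation about z by `deg` then translation)
rigid_move <- function(model, deg = 0, shift = c(0, 0, 0)) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

# random 3D point set as a structure-model-free matrix
random_points <- function(n, scale = 2) {
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}

# wrap a raw n x 3 point set as a CA-only structure model
points_model <- function(P) {
  make_structure(lapply(seq_len(nrow(P)), function(i)
    list("CA", "ALA", "A", i, P[i, 1], P[i, 2], P[i, 3])))
}

# package-route RMSD for raw point sets (via the full superposition API)
kabsch_points_rmsd <- function(P, Q) {
  kabsch_superpose(points_model(P), points_model(Q),
                   atom_set = "CA")$global_rmsd
}

write_tsv_tmp <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  f
}
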