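# shared fixture builders: raw PDB text, minimal atom tables, oracles

pdb_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                     occ = 1.0, b = 0.0, elem = "C", altloc = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, altloc, resid, chain, resno, x, y, z, occ, b, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# bare atom table (already radius-assigned carbons unless stated)
mk_atoms <- function(xyz, serial = seq_len(nrow(xyz)), resno = serial,
                     chain = "A", element = "C", radius = 1.87) {
  xyz <- as.matrix(xyz)
  d <- data.frame(serial = as.integer(serial), name = "CA", element = element,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  chain = chain, resno = as.integer(resno), insert = "",
                  resid = "GLY", occ = 1, altloc = "", is_hetero = FALSE,
                  radius = radius, stringsAsFactors = FALSE)
  d$res_key <- sprintf("%s:%d:", d$chain, d$resno)
  d
}

mk_cmap <- function(grades, chain = "A", resno = seq_along(grades)) {
  structure(stats::setNames(as.integer(grades),
                            sprintf("%s:%d:", chain, resno)),
            class = "conservation_map")
}

# independent single-linkage oracle: union-find over all pairs
uf_components <- function(xyz, d) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= d) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}

# LP membership: is point p inside the convex hull of rows of X?
# feasibility of  X^T lambda = p, sum lambda = 1, lambda >= 0
in_hull_lp <- function(p, X) {
  n <- nrow(X)
  r <- boot::simplex(a = rep(0, n), A3 = rbind(t(X), rep(1, n)), b3 = c(p, 1))
  r$solved == 1
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_atoms <- function(atoms, rot, shift) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
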