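# Shared test builders: tiny PDB snippets and geometric ligands built in
# code, plus brute-force oracles kept deliberately independent of the
# package internals they check.

atom_rec <- function(rec, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", element = substr(name, 1, 1)) {
  nm <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name),
               sprintf("%-4s", name))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, altloc, resname, chain, resno, x, y, z, occ, 0,
          toupper(element))
}

gly_chain_pdb <- function() {
  paste(c(
    atom_rec("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
    atom_rec("ATOM", 2, "CA", "GLY", "A", 1, 1.45, 0, 0, element = "C"),
    atom_rec("ATOM", 3, "C", "GLY", "A", 1, 2.0, 1.4, 0, element = "C")),
    collapse = "\n")
}

# regular hexagon of C with optional het code / CONECT
hexagon_het_pdb <- function(het = "BNZ", conect = TRUE, r = 1.39, z = 0) {
  ang <- (0:5) * pi / 3
  lines <- atom_rec("HETATM", 1:6, paste0("C", 1:6), het, "A", 401,
                    r * cos(ang), r * sin(ang), rep(z, 6), element = "C")
  if (conect)
    lines <- c(lines, sprintf("CONECT%5d%5d", 1:6, c(2:6, 1)))
  paste(c(lines, "END"), collapse = "\n")
}

# ligand object straight from geometry (bypasses PDB text)
make_ligand <- function(elements, xyz, bonds = NULL, het = "LIG") {
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  structure(list(
    het_code = het, chain = "A", resno = 1L,
    atoms = data.frame(serial = seq_along(elements),
                       name = paste0(elements, seq_along(elements)),
                       element = elements,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       occupancy = 1, stringsAsFactors = FALSE),
    bonds = bonds, aromatic = rep(FALSE, length(elements)),
    perceived = FALSE, charges = NULL), class = "lsr_ligand")
}

hexagon_xyz <- function(r = 1.39, z = 0) {
  ang <- (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), rep(z, 6))
}

ring_bonds <- function(order = "ar") {
  data.frame(i = 1:6, j = c(2:6, 1), order = order, stringsAsFactors = FALSE)
}

# 3-methylcatechol ligand: ring C1..C6, O on C1 and C2, methyl on C3
methylcatechol_ligand <- function(het = "MCT") {
  ring <- hexagon_xyz()
  sub <- function(k, bond) ring[k, ] * (1 + bond / 1.39)
  xyz <- rbind(ring, sub(1, 1.36), sub(2, 1.36), sub(3, 1.50))
  make_ligand(c(rep("C", 6), "O", "O", "C"), xyz,
              data.frame(i = c(1:6, 1, 2, 3), j = c(2:6, 1, 7, 8, 9),
                         order = "1", stringsAsFactors = FALSE), het = het)
}

random_rotation_matrix <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr(m)
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# deterministic planted fingerprint blobs: g well-separated bit-vector
# centers, each point flips a few bits of its center (separation >> spread)
planted_blobs <- function(g, per = 12, nbits = 256, flip = 4, seed = 1) {
  set.seed(seed)
  centers <- matrix(0L, g, nbits)
  for (i in seq_len(g)) centers[i, sample(nbits, 40)] <- 1L
  x <- matrix(0L, g * per, nbits)
  lab <- rep(seq_len(g), each = per)
  for (r in seq_len(nrow(x))) {
    v <- centers[lab[r], ]
    fl <- sample(nbits, flip)
    v[fl] <- 1L - v[fl]
    x[r, ] <- v
  }
  list(x = x, labels = lab)
}

# same, sized to a total point count
planted_blobs_acc <- function(g, n_total = 200, nbits = 256, flip = 4,
                              seed = 1) {
  planted_blobs(g, per = ceiling(n_total / g), nbits = nbits, flip = flip,
                seed = seed)
}

# brute-force capture oracle: plain double loop over atoms x centers
capture_oracle <- function(centers, xyz, radius) {
  hit <- logical(nrow(xyz))
  for (i in seq_len(nrow(xyz)))
    for (j in seq_len(nrow(centers)))
      if (sqrt(sum((xyz[i, ] - centers[j, ])^2)) <= radius) hit[i] <- TRUE
  which(hit)
}

# brute-force silhouette oracle (direct formula, no vectorization tricks)
silhouette_oracle <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, which(labels == l)]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# brute-force subgraph-match oracle: try all injections of the query core
# into the ligand atoms (tiny graphs only)
match_oracle_count <- function(ligand, query) {
  core <- query$core
  nq <- length(core)
  qel <- query$atoms$element[core]
  qar <- query$atoms$aromatic[core]
  qmap <- match(seq_len(nrow(query$atoms)), core)
  qb <- query$bonds
  in_core <- !is.na(qmap[qb$i]) & !is.na(qmap[qb$j])
  qpairs <- cbind(qmap[qb$i[in_core]], qmap[qb$j[in_core]])
  qcls <- ifelse(qb$order[in_core] == "ar", "ar", "s")
  att <- integer(nq)
  for (k in which(!in_core)) {
    ends <- c(qb$i[k], qb$j[k])
    cn <- ends[!query$atoms$is_attachment[ends]]
    att[qmap[cn]] <- att[qmap[cn]] + 1L
  }
  nl <- nrow(ligand$atoms)
  lb <- ligand$bonds
  lcls <- matrix("", nl, nl)
  adj <- matrix(FALSE, nl, nl)
  for (r in seq_len(nrow(lb))) {
    adj[lb$i[r], lb$j[r]] <- adj[lb$j[r], lb$i[r]] <- TRUE
    cls <- ifelse(lb$order[r] == "ar", "ar", "s")
    lcls[lb$i[r], lb$j[r]] <- lcls[lb$j[r], lb$i[r]] <- cls
  }
  found <- character(0)
  perms <- gtools_permutations(nl, nq)
  for (p in seq_len(nrow(perms))) {
    m <- perms[p, ]
    ok <- all(ligand$atoms$element[m] == qel) &&
      all(ligand$aromatic[m] == qar)
    if (!ok) next
    for (r in seq_len(nrow(qpairs))) {
      a <- m[qpairs[r, 1]]; b <- m[qpairs[r, 2]]
      if (!adj[a, b] || lcls[a, b] != qcls[r]) { ok <- FALSE; break }
    }
    if (!ok) next
    for (k in which(att > 0)) {
      outside <- setdiff(which(adj[m[k], ]), m)
      if (length(outside) < att[k]) { ok <- FALSE; break }
    }
    if (ok) found <- c(found, paste(sort(m), collapse = ","))
  }
  length(unique(found))
}

# all ordered selections of r items from n (small n only)
gtools_permutations <- function(n, r) {
  if (r == 0) return(matrix(integer(0), 1, 0))
  recurse <- function(chosen) {
    if (length(chosen) == r) return(matrix(chosen, 1))
    rest <- setdiff(seq_len(n), chosen)
    do.call(rbind, lapply(rest, function(x) recurse(c(chosen, x))))
  }
  recurse(integer(0))
}
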