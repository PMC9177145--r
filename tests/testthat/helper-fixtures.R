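# Shared fixtures: all inputs are generated in code at test time.

AA <- hlacpep:::AA20

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_peptides <- function(n, length = 9L, seed = 1L) {
  withr::with_seed(seed, {
    replicate(n, paste(sample(AA, length, replace = TRUE), collapse = ""))
  })
}

# build + load a toy structure, silencing chain-detection logs
toy_model <- function(..., ext = ".cif", group = "C1",
                      heavy_length = 180L) {
  f <- tempfile(fileext = ext)
  build_toy_structure(toy_structure_spec(..., heavy_length = heavy_length), f)
  suppressMessages(load_structure(f, group = group))
}

# random proper rotation (det +1) via QR
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# apply a rigid-body transform to every atom of a loaded structure
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# craft a minimal groove_structure directly from an atom table (for tests
# of atom-class handling that need unphysical decoys)
fake_model <- function(atoms, heavy = "A", pep = "P") {
  structure(list(id = "fake", atoms = atoms, heavy_chain = heavy,
                 peptide_chain = pep,
                 pep_resnos = sort(unique(atoms$resno[atoms$chain == pep])),
                 group = "C1", offset = 0L),
            class = "groove_structure")
}

atom_row <- function(chain, resno, elety, resid, x, y, z) {
  data.frame(chain = chain, resno = resno, elety = elety, resid = resid,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# panel of (allotype, pfm) entries built from explicit frequency matrices
panel_from_freqs <- function(freqs_c1, freqs_c2, n = 0L) {
  mk <- function(freq, name, g) {
    r <- if (g == "C1") c("S", "N") else c("N", "K")
    list(allotype = allotype_record(name, r[1], r[2]),
         pfm = hlacpep:::pfm_from_freq(freq, n = n))
  }
  c(mapply(mk, freqs_c1, sprintf("C1-%02d", seq_along(freqs_c1)),
           MoreArgs = list(g = "C1"), SIMPLIFY = FALSE),
    mapply(mk, freqs_c2, sprintf("C2-%02d", seq_along(freqs_c2)),
           MoreArgs = list(g = "C2"), SIMPLIFY = FALSE))
}

# enumeration oracle for the two-sided Fisher p: binomial-coefficient table
# probabilities, summing those no more probable than the observed table
fisher_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  ks <- max(0, K - n2):min(K, n1)
  pr <- choose(n1, ks) * choose(n2, K - ks) / choose(N, K)
  obs <- pr[ks == k1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}
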