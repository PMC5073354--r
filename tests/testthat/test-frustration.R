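test_that("contact potential and energy behave as documented", {
  M <- contact_potential()
  expect_equal(M, t(M))                                 # symmetric table
  expect_equal(contact_energy("ALA", "TRP", 5),
               contact_energy("TRP", "ALA", 5))
  expect_equal(contact_energy("LYS", "ASP", 5), M["LYS", "ASP"])
  expect_equal(contact_energy("ILE", "ILE", 12), 0)     # beyond outer switch
  expect_error(contact_energy("XXX", "ALA", 5), "unknown residue")
  # hand-computed entry: Ile-Leu = -(4.5/4.5)*(3.8/4.5); Lys-Lys = +1
  expect_equal(M["ILE", "LEU"], -(4.5 / 4.5) * (3.8 / 4.5), tolerance = 1e-12)
  expect_equal(M["LYS", "LYS"], 1, tolerance = 1e-12)
  # switch: half weight at the midpoint of the roll-off window
  expect_equal(contact_energy("ILE", "ILE", 8.0),
               0.5 * M["ILE", "ILE"], tolerance = 1e-12)
})

test_that("build_contacts equals brute-force enumeration and honours seq sep", {
  set.seed(55)
  s <- make_helix(30, sequence = sample(c("ALA", "ILE", "LYS", "ASP", "GLY"),
                                        30, TRUE), jitter_sd = 0.3)
  for (cutoff in c(7, 9.5, 12)) for (sep in c(1L, 3L, 5L)) {
    ct <- build_contacts(s, cutoff, sep)
    # oracle: all-pairs over Cb (Ca for Gly) centres
    idx <- atom_select(s, sel_protein())
    keys <- residue_keys(s)[idx]; uk <- unique(keys)
    centers <- t(vapply(uk, function(k) {
      rows <- idx[keys == k]
      cb <- rows[s$atoms$atom[rows] == "CB"]
      if (s$atoms$resname[rows[1]] != "GLY" && length(cb) == 1) coords(s)[cb, ]
      else coords(s)[rows[s$atoms$atom[rows] == "CA"], ]
    }, numeric(3)))
    n_oracle <- 0L
    for (i in 1:(nrow(centers) - 1)) for (j in (i + 1):nrow(centers)) {
      if (j - i >= sep && sqrt(sum((centers[i, ] - centers[j, ])^2)) <= cutoff)
        n_oracle <- n_oracle + 1L
    }
    expect_equal(nrow(ct), n_oracle)
    if (nrow(ct) > 0) expect_true(all(ct$j - ct$i >= sep))
  }
  # two residues 20 A apart never contact at 9.5
  far <- structure_from_coords(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(nrow(build_contacts(far, 9.5, 1L)), 0L)
})

test_that("exhaustive and sampled frustration agree within MC error", {
  h <- make_helix(20, sequence = c("ILE", "LYS", "ASP", "ALA"))
  ct <- build_contacts(h, 9.5, 3L)
  ex <- mutational_frustration(ct, exhaustive = TRUE)
  sm <- mutational_frustration(ct, n_decoys = 10000L, seed = 42)
  # the MC error of a z-score exceeds 1/sqrt(n) (mean and sd are both
  # estimated from a discrete, skewed decoy distribution), so the error bar
  # is the empirical per-contact SE over independent sampling replicates;
  # 3.5 SEs allows for taking the max over all contacts
  reps <- sapply(1:8, function(s)
    mutational_frustration(ct, n_decoys = 10000L, seed = 100 + s)$frustration)
  se <- apply(reps, 1, sd)
  expect_lt(max(abs(ex$frustration - sm$frustration) / se), 3.5)
  # bit-reproducible under a fixed seed
  expect_identical(mutational_frustration(ct, 500L, seed = 7)$frustration,
                   mutational_frustration(ct, 500L, seed = 7)$frustration)
})

test_that("planted table-optimal native pair maximises F; degenerate is neutral", {
  M <- contact_potential()
  best <- which(M == min(M), arr.ind = TRUE)[1, ]
  best_pair <- rownames(M)[best]                        # table-global optimum
  seqs <- rep("GLY", 20)
  seqs[c(5, 9)] <- best_pair                            # residues 5 and 9 touch
  h <- make_helix(20, sequence = seqs)
  net <- frustration_network(h, exhaustive = TRUE)
  ct <- net$contacts
  planted <- ct$resseq_i == 5 & ct$resseq_j == 9
  expect_true(any(planted))
  expect_gt(ct$frustration[planted], 0)
  expect_equal(max(ct$frustration), ct$frustration[planted])
  # exact exhaustive value: z-score of the native energy over all 400 pairs
  # (the distance weight scales decoys and native alike, so it cancels)
  ed <- as.numeric(M)
  expect_equal(ct$frustration[planted],
               (mean(ed) - M[best_pair[1], best_pair[2]]) / sd(ed),
               tolerance = 1e-9)

  # uniform potential through zero-weight distance: F undefined -> neutral
  lone <- structure_from_coords(rbind(c(0, 0, 0), c(5, 0, 0), c(9.4, 0, 0),
                                      c(14, 0, 0), c(18, 0, 0)))
  ct0 <- build_contacts(lone, 20, 1L)
  ct0$distance <- 12                                    # all beyond the switch
  expect_warning(f0 <- mutational_frustration(ct0, exhaustive = TRUE),
                 "degenerate")
  expect_true(all(is.na(f0$frustration)))
  expect_true(all(classify_frustration(f0$frustration) == "neutral"))
})

test_that("classification thresholds split minimal/neutral/high", {
  expect_equal(classify_frustration(c(2, -2, 0, 0.78, -1, NA)),
               c("minimal", "high", "neutral", "minimal", "high", "neutral"))
})

test_that("a natively well-packed fixture is mostly minimally frustrated", {
  # hydrophobic-core sequence: every contact is a favourable pair
  h <- make_helix(25, sequence = c("ILE", "LEU", "VAL", "PHE"))
  net <- frustration_network(h, exhaustive = TRUE)
  expect_gte(mean(net$contacts$class == "minimal"), 0.8)
})

test_that("frustration_path: planted chain, no-path, and BFS oracle", {
  mknet <- function(edges, F = -2) {
    ct <- data.frame(i = edges$a, j = edges$b, chain_i = "A",
                     resseq_i = edges$a, resname_i = "ALA", chain_j = "A",
                     resseq_j = edges$b, resname_j = "ALA", distance = 5,
                     native_energy = 1,
                     frustration = if (length(F) == 1) rep(F, nrow(edges)) else F)
    ct$class <- classify_frustration(ct$frustration)
    structure(list(contacts = ct, fractions = c(0, 0, 1),
                   thresholds = c(minimal = 0.78, high = -1)),
              class = "FrustrationNetwork")
  }
  chain <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))
  p <- frustration_path(mknet(chain), 1, 4)
  expect_true(p$found)
  expect_equal(p$path, c(1L, 2L, 3L, 4L))
  expect_equal(p$n_edges, 3L)

  # no high-frustration contacts at all -> explicit no-path
  p0 <- frustration_path(mknet(chain, F = 2), 1, 4)
  expect_false(p0$found)
  expect_error(frustration_path(mknet(chain), integer(0), 4), "non-empty")

  # tie-break: two 2-edge routes, the more frustrated one wins
  tie <- data.frame(a = c(1, 2, 1, 3), b = c(2, 4, 3, 4))
  pt <- frustration_path(mknet(tie, F = c(-2, -2, -5, -5)), 1, 4)
  expect_equal(pt$path, c(1L, 3L, 4L))
  expect_equal(pt$sum_absF, 10)

  # random planted graphs vs breadth-first-search oracle
  set.seed(66)
  for (rep in 1:50) {
    n <- sample(6:25, 1)
    m <- sample(5:40, 1)
    edges <- unique(data.frame(a = sample(n, m, TRUE), b = sample(n, m, TRUE)))
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    if (nrow(edges) == 0) next
    sa <- sample(n, 2); sb <- sample(n, 2)
    got <- frustration_path(mknet(edges), sa, sb)
    want <- bfs_path_length(edges, sa, sb)
    if (any(sa %in% sb)) next   # overlapping sites: length-0 path, skip both
    if (is.na(want)) expect_false(got$found)
    else expect_equal(got$n_edges, want)
  }
})
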