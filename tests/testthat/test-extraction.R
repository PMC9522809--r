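# Lattice labeling and the inverse retrieval operations.

# deterministic toy setup: a 4x3 grid, hand-placed BMU assignments
make_toy_labels <- function() {
  asg <- data.frame(
    molecule_id = c("m1", "m2", "m3", "m4", "m5"),
    H = c(1L, 1L, 3L, 0L, 2L),
    V = c(2L, 2L, 0L, 0L, 1L),
    distance = c(0.1, 0.2, 0.3, 0.4, 0.5))
  attr(asg, "width") <- 4L
  attr(asg, "height") <- 3L
  class(asg) <- c("bmu_assignment", "data.frame")
  tab <- descriptor_table_sets(
    list(m1 = c("peach"), m2 = c("coconut"), m3 = c("spicy", "warm"),
         m4 = character(), m5 = c("spicy")))
  list(assignments = asg, table = tab)
}

descriptor_table_sets <- function(sets) {
  ids <- names(sets)
  all_d <- sort(unique(unlist(sets)))
  mat <- matrix(0L, length(ids), length(all_d),
                dimnames = list(ids, all_d))
  for (i in seq_along(ids)) mat[i, sets[[i]]] <- 1L
  descriptor_table(ids, all_d, mat)
}

toy_latents <- function(ids = paste0("m", 1:5), d = 4L, seed = 5L) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(length(ids) * d)) + 0.01, length(ids), d,
                 dimnames = list(ids, NULL))
  structure(list(molecule_ids = ids, values = vals),
            class = "latent_matrix")
}

test_that("lattice labels are unions of member descriptor sets", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  # m1 {peach} and m2 {coconut} share BMU (1,2): union label set
  n12 <- labels$neurons[[2 * 4 + 1 + 1]]
  expect_setequal(n12$members, c("m1", "m2"))
  expect_setequal(n12$labels, c("coconut", "peach"))
  # descriptor-less m4 is a member but adds no labels
  n00 <- labels$neurons[[1]]
  expect_equal(n00$members, "m4")
  expect_equal(n00$labels, character())
  # membership conservation: every molecule in exactly one neuron
  all_members <- unlist(lapply(labels$neurons, `[[`, "members"))
  expect_setequal(all_members, toy$assignments$molecule_id)
  expect_equal(length(all_members), 5L)
  # label set invariant holds at every neuron
  for (n in labels$neurons)
    expect_equal(sort(n$labels),
                 sort(as.character(unique(unlist(n$member_descriptors)))))
})

test_that("descriptor exclusion list drops labels but keeps members", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table, exclude = "peach")
  n12 <- labels$neurons[[2 * 4 + 1 + 1]]
  expect_setequal(n12$members, c("m1", "m2"))
  expect_equal(n12$labels, "coconut")
  expect_warning(gone <- neurons_for_descriptor(labels, "peach"),
                 "not found")
  expect_equal(nrow(gone), 0L)
})

test_that("neurons_for_descriptor scans the lattice in row-major order", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  # descriptor carried by one molecule: exactly its BMU
  expect_equal(neurons_for_descriptor(labels, "peach"),
               cbind(H = 1L, V = 2L))
  # spicy occurs at (3,0) and (2,1): row-major order
  spicy <- neurons_for_descriptor(labels, "spicy")
  expect_equal(unname(spicy), rbind(c(3L, 0L), c(2L, 1L)))
  # unknown descriptor: empty with warning, not an error
  expect_warning(none <- neurons_for_descriptor(labels, "vanilla"),
                 "not found")
  expect_equal(nrow(none), 0L)
  # brute-force scan oracle
  brute <- do.call(rbind, lapply(labels$neurons, function(n)
    if ("spicy" %in% n$labels) c(n$H, n$V)))
  expect_equal(unname(spicy), brute)
})

test_that("descriptor-pair modes distinguish neuron- and molecule-level
           co-occurrence", {
  # one neuron holds {spicy} and {warm} on different molecules, another
  # holds both on one molecule
  asg <- data.frame(molecule_id = c("a", "b", "c"),
                    H = c(0L, 0L, 1L), V = c(0L, 0L, 0L),
                    distance = 0)
  attr(asg, "width") <- 2L; attr(asg, "height") <- 1L
  class(asg) <- c("bmu_assignment", "data.frame")
  tab <- descriptor_table_sets(list(a = "spicy", b = "warm",
                                    c = c("spicy", "warm")))
  labels <- label_lattice(asg, tab)
  on_neuron <- neurons_for_descriptor_pair(labels, "spicy", "warm",
                                           "both_on_neuron")
  on_mol <- neurons_for_descriptor_pair(labels, "spicy", "warm",
                                        "both_on_molecule")
  expect_equal(unname(on_neuron), rbind(c(0L, 0L), c(1L, 0L)))
  expect_equal(unname(on_mol), rbind(c(1L, 0L)))
  # no co-occurrence at all
  expect_equal(nrow(neurons_for_descriptor_pair(labels, "spicy",
                                                "vanilla")), 0L)
})

test_that("both_on_molecule is a subset of both_on_neuron on generated
           data", {
  ds <- sample_dataset(tiny_generator(seed = 21L))
  lat <- toy_latents(ids = ds$truth$molecule_id, d = 3L)
  grid <- toy_grid(width = 5L, height = 4L, d = 3L, seed = 2L)
  labels <- label_lattice(bmu_assignments(grid, lat), ds$descriptors)
  pool <- ds$descriptors$descriptor_names
  for (i in seq_len(min(6, length(pool) - 1))) {
    d1 <- pool[i]; d2 <- pool[i + 1]
    nn <- neurons_for_descriptor_pair(labels, d1, d2, "both_on_neuron")
    nm <- neurons_for_descriptor_pair(labels, d1, d2, "both_on_molecule")
    key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character()
    expect_true(all(key(nm) %in% key(nn)))
  }
})

test_that("locate_molecule finds BMUs and suggests near-matches", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  expect_equal(locate_molecule(labels, "m3"), c(H = 3L, V = 0L))
  expect_error(locate_molecule(labels, "M3"), "did you mean.*m3")
  # agrees with per-row assignment (find_bmu consistency)
  for (r in seq_len(nrow(toy$assignments)))
    expect_equal(unname(locate_molecule(labels,
                                        toy$assignments$molecule_id[r])),
                 c(toy$assignments$H[r], toy$assignments$V[r]))
})

test_that("inverse_map returns members, latents and reference scores", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  lat <- toy_latents()
  res <- inverse_map(labels, lat, c(1, 2), reference_id = "m1")
  expect_setequal(res$member_ids, c("m1", "m2"))
  expect_equal(nrow(res$member_latents), 2L)
  # self-similarity of the reference is exactly 1
  expect_equal(unname(res$similarity_to_reference[["m1"]]), 1)
  expect_equal(unname(res$similarity_to_reference[["m2"]]),
               cosine_similarity(lat$values["m2", ], lat$values["m1", ]))
  # single-member neuron, self-reference
  solo <- inverse_map(labels, lat, c(3, 0), reference_id = "m3")
  expect_equal(solo$member_ids, "m3")
  expect_equal(unname(solo$similarity_to_reference), 1)
  # empty neuron: empty result with warning
  expect_warning(empty <- inverse_map(labels, lat, c(3, 2)), "no member")
  expect_length(empty$member_ids, 0L)
  # member set equals brute-force filter of the assignments
  brute <- toy$assignments$molecule_id[toy$assignments$H == 1 &
                                       toy$assignments$V == 2]
  expect_setequal(res$member_ids, brute)
})

test_that("extraction closure: every molecule is in its own neuron's
           extraction", {
  ds <- sample_dataset(tiny_generator(seed = 31L))
  lat <- toy_latents(ids = ds$truth$molecule_id, d = 3L, seed = 9L)
  grid <- toy_grid(width = 5L, height = 4L, d = 3L, seed = 4L)
  labels <- label_lattice(bmu_assignments(grid, lat), ds$descriptors)
  for (id in sample(ds$truth$molecule_id, 10)) {
    res <- inverse_map(labels, lat, locate_molecule(labels, id))
    expect_true(id %in% res$member_ids)
  }
  # membership conservation across the whole lattice
  expect_equal(sum(vapply(labels$neurons,
                          function(n) length(n$members), integer(1))),
               nrow(ds$truth))
})

test_that("nearest_neuron honors the predicate, exclusion and tie-break", {
  grid <- toy_grid(width = 4L, height = 3L, d = 4L, seed = 6L)
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  # from spicy+warm neuron (3,0), nearest spicy-only neuron is (2,1)
  hit <- nearest_neuron(grid, labels, c(3, 0), function(ls)
    "spicy" %in% ls && !("warm" %in% ls))
  expect_equal(hit, c(H = 2L, V = 1L))
  # `from` itself never returned even when it satisfies the predicate
  expect_error(nearest_neuron(grid, labels, c(3, 0), function(ls)
    "warm" %in% ls), "no neuron")
  # exhaustive-scan oracle over a permissive predicate
  pred <- function(ls) length(ls) > 0
  hit2 <- nearest_neuron(grid, labels, c(0, 0), pred)
  pos <- grid$positions
  from_i <- 0 * 4 + 0 + 1
  cand <- which(vapply(labels$neurons, function(n)
    pred(n$labels), logical(1)))
  cand <- setdiff(cand, from_i)
  d2 <- (pos[cand, 1] - pos[from_i, 1])^2 +
        (pos[cand, 2] - pos[from_i, 2])^2
  best <- cand[which.min(d2)]
  expect_equal(unname(hit2), c((best - 1) %% 4, (best - 1) %/% 4))
})

test_that("label table and extraction report export cleanly", {
  toy <- make_toy_labels()
  labels <- label_lattice(toy$assignments, toy$table)
  tab <- lattice_label_table(labels)
  expect_equal(nrow(tab), 12L)
  expect_equal(sum(tab$n_members), 5L)
  expect_equal(tab$labels[tab$H == 1 & tab$V == 2], "coconut;peach")
  rep <- extraction_report(inverse_map(labels, toy_latents(), c(1, 2),
                                       reference_id = "m1"))
  expect_equal(nrow(rep), 2L)
  expect_true(all(c("molecule_id", "H", "V", "descriptors",
                    "similarity_to_reference") %in% names(rep)))
})
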