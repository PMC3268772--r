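# Five-level storage forest, placements, movement history.

test_that("a five-level chain is built and level 6 is refused", {
  fx <- basic_fixture()
  db <- fx$db
  lvl <- storage_tree(db)
  expect_equal(sort(lvl$level), 1:5)
  expect_error(add_storage_node(db, "Sub-box", fx$nodes$box),
               class = "genolims_depth_exceeded")
})

test_that("the storage model is a forest with sibling-unique names", {
  db <- tmp_db()
  a <- add_storage_node(db, "Lab A")
  b <- add_storage_node(db, "Lab B")
  expect_equal(node_level(db, a), 1L)
  expect_equal(node_level(db, b), 1L)
  r1 <- add_storage_node(db, "Rack", a)
  expect_error(add_storage_node(db, "Rack", a), class = "genolims_rule_violation")
  expect_silent(add_storage_node(db, "Rack", b))     # same name, other parent
  expect_error(add_storage_node(db, "Lab A"), class = "genolims_rule_violation")
  # moves that would create cycles or exceed depth are refused
  expect_error(move_storage_node(db, a, r1), class = "genolims_tree_cycle")
})

test_that("remove_node only removes empty leaves", {
  fx <- basic_fixture()
  db <- fx$db
  expect_error(remove_storage_node(db, fx$nodes$rack),
               class = "genolims_node_not_empty")
  place_item(db, "sample", fx$smp, fx$nodes$box, "2024-01-01")
  expect_error(remove_storage_node(db, fx$nodes$box),
               class = "genolims_node_occupied")
  check_out_item(db, "sample", fx$smp, "2024-02-01")
  expect_true(remove_storage_node(db, fx$nodes$box))
})

test_that("placement requires a leaf and a free item; history is kept", {
  fx <- basic_fixture()
  db <- fx$db
  expect_error(place_item(db, "sample", fx$smp, fx$nodes$shelf, "2024-01-01"),
               class = "genolims_not_leaf")
  place_item(db, "sample", fx$smp, fx$nodes$box, "2024-01-01")
  expect_error(place_item(db, "sample", fx$smp, fx$nodes$box, "2024-01-02"),
               class = "genolims_already_placed")
  # locate o place is the identity on the leaf
  path <- locate_item(db, "sample", fx$smp)
  expect_equal(path$storage_id[nrow(path)], fx$nodes$box)
  expect_equal(nrow(path), 5L)
  expect_equal(format_storage_path(path), "Lab / Freezer / Shelf / Rack / Box")
  # move: check out, place elsewhere, two placements retained, one open
  box2 <- add_storage_node(db, "Box 2", fx$nodes$rack)
  check_out_item(db, "sample", fx$smp, "2024-02-01")
  place_item(db, "sample", fx$smp, box2, "2024-02-02")
  hist <- search_records(db, "storage_samples")
  expect_equal(nrow(hist), 2L)
  expect_equal(sum(is.na(hist$date_out)), 1L)
  expect_error(check_out_item(db, "sample", fx$smp, "2023-01-01"),
               class = "genolims_invalid_value")
})

test_that("shallow labs work: a level-2 leaf yields a length-2 path", {
  fx <- basic_fixture()
  db <- fx$db
  lab_b <- add_storage_node(db, "Lab B")
  fridge <- add_storage_node(db, "Fridge", lab_b)
  place_item(db, "sample", fx$smp, fridge, "2024-01-01")
  expect_equal(nrow(locate_item(db, "sample", fx$smp)), 2L)
  expect_error(locate_item(db, "dna", 1L), class = "genolims_not_found")
})

test_that("list_subtree_items equals the brute-force ancestor scan", {
  fx <- basic_fixture()
  db <- fx$db
  mt <- get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id
  ids <- register_samples(db, data.frame(
    organism_id = rep(fx$org, 99L), project_id = fx$proj,
    material_type_id = mt))
  ids <- c(fx$smp, ids)
  # second branch of the tree
  f2 <- add_storage_node(db, "Freezer 2", fx$nodes$lab)
  box2 <- add_storage_node(db, "Box A", f2)
  leaves <- c(fx$nodes$box, box2)
  set.seed(99)
  place_items(db, data.frame(
    item_type = "sample", item_id = ids,
    storage_id = sample(leaves, length(ids), replace = TRUE),
    date_in = "2024-01-01"))

  ancestors <- function(node) {
    out <- node
    tab <- search_records(db, "storage")
    repeat {
      p <- tab$parent_id[match(node, tab$storage_id)]
      if (is.na(p)) break
      out <- c(out, p); node <- p
    }
    out
  }
  open <- search_records(db, "storage_samples")
  open <- open[is.na(open$date_out), ]
  for (root in c(fx$nodes$lab, f2, fx$nodes$box)) {
    got <- sort(list_subtree_items(db, root)$item_id)
    want <- sort(open$item_id[vapply(open$storage_id, function(n)
      root %in% ancestors(n), TRUE)])
    expect_equal(got, want, info = paste("root", root))
  }
  # conservation: items over all roots equal total open placements
  roots <- search_records(db, "storage")
  roots <- roots$storage_id[is.na(roots$parent_id)]
  expect_equal(sum(vapply(roots, function(r)
    nrow(list_subtree_items(db, r)), 0L)), nrow(open))
})

test_that("forest and depth invariants survive random operation sequences", {
  db <- tmp_db()
  set.seed(7)
  nodes <- c(add_storage_node(db, "root1"), add_storage_node(db, "root2"))
  n_err <- 0L
  for (i in 1:60) {
    op <- sample(c("add", "remove", "move", "rename"), 1L,
                 prob = c(0.55, 0.15, 0.2, 0.1))
    res <- tryCatch({
      if (op == "add") {
        parent <- if (runif(1) < 0.15) NULL else sample(nodes, 1L)
        nodes <- c(nodes, add_storage_node(db, paste0("n", i), parent))
      } else if (op == "remove" && length(nodes) > 2L) {
        victim <- sample(nodes, 1L)
        remove_storage_node(db, victim)
        nodes <- setdiff(nodes, victim)
      } else if (op == "move" && length(nodes) > 2L) {
        move_storage_node(db, sample(nodes, 1L), sample(nodes, 1L))
      } else if (op == "rename") {
        rename_storage_node(db, sample(nodes, 1L), paste0("r", i))
      }
      TRUE
    }, genolims_error = function(e) { n_err <<- n_err + 1L; FALSE })
    tab <- storage_tree(db)
    expect_false(anyNA(tab$level))          # connected to a root: no cycle
    expect_true(all(tab$level <= 5L))       # depth bound
    # sibling names unique (NULL parents form one sibling group)
    key <- paste(ifelse(is.na(tab$parent_id), 0L, tab$parent_id),
                 tab$storage_name)
    expect_false(anyDuplicated(key) > 0L)
  }
  expect_gt(n_err, 0L)  # the sequence actually exercised refusals
})
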