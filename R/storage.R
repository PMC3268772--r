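# Physical storage locations as a five-level tree kept as an adjacency
# list in the single `storage` relation (storage_id, storage_name,
# parent_id).  Samples and DNA are placed at leaf nodes via the
# `storage_samples` relation; re-placement requires an explicit check-out,
# so the movement history stays auditable.

MAX_STORAGE_DEPTH <- 5L

storage_node <- function(db, node) {
  r <- db_get(db, "storage", node)
  if (is.null(r))
    stop_genolims(paste0("no storage node with id ", node), "genolims_not_found")
  r
}

#' Level of a storage node (root-distance + 1)
#' @param db A database handle.
#' @param node Node id.
#' @export
node_level <- function(db, node) length(node_path_ids(db, node))

node_path_ids <- function(db, node) {
  path <- integer(0)
  cur <- node
  repeat {
    r <- storage_node(db, cur)
    path <- c(cur, path)
    if (is.na(r$parent_id)) break
    cur <- r$parent_id
    if (length(path) > MAX_STORAGE_DEPTH + 1L)
      stop_genolims("storage tree is corrupted (cycle or over-deep chain)",
                    "genolims_tree_corrupt")
  }
  path
}

node_children <- function(db, node) {
  dbGetQuery(db$con,
    "SELECT * FROM storage WHERE parent_id = ? ORDER BY storage_id",
    params = list(node))
}

is_leaf <- function(db, node) nrow(node_children(db, node)) == 0L

#' Add a storage location node
#'
#' Creates a node under `parent` (or a new root).  The tree is a forest of
#' depth at most five: level 1 is the storage location (lab, room), level 5
#' the sample storage itself (box or vessel); adding below level 5 is
#' refused.  Names must be unique among siblings.
#'
#' @param db A database handle.
#' @param name Node label.
#' @param parent Parent node id, or `NULL` for a new root.
#' @return The new node id, invisibly.
#' @examples
#' db <- init_schema(tempfile(fileext = ".db"))
#' lab <- add_storage_node(db, "Lab A")
#' frz <- add_storage_node(db, "Freezer 1", parent = lab)
#' lims_close(db)
#' @export
add_storage_node <- function(db, name, parent = NULL) {
  authz(db, task = "f", action = "write")
  if (!is.null(parent)) {
    lvl <- node_level(db, parent)
    if (lvl >= MAX_STORAGE_DEPTH)
      stop_genolims(sprintf(
        "cannot add below level %d ('%s' is at the lowest storage level)",
        MAX_STORAGE_DEPTH, storage_node(db, parent)$storage_name),
        "genolims_depth_exceeded")
  }
  invisible(db_insert(db, "storage",
                      list(storage_name = name, parent_id = parent)))
}

#' Remove an empty storage node
#'
#' A node can be removed only when it has no children and no open
#' placements.
#'
#' @param db A database handle.
#' @param node Node id.
#' @export
remove_storage_node <- function(db, node) {
  authz(db, task = "f", action = "delete")
  storage_node(db, node)
  if (nrow(node_children(db, node)) > 0L)
    stop_genolims("node has children", "genolims_node_not_empty")
  open <- dbGetQuery(db$con,
    "SELECT COUNT(*) AS n FROM storage_samples
      WHERE storage_id = ? AND date_out IS NULL", params = list(node))$n
  if (open > 0L)
    stop_genolims("node is occupied (open placements)", "genolims_node_occupied")
  db_delete(db, "storage", node)
  invisible(TRUE)
}

#' Rename a storage node
#' @param db A database handle.
#' @param node Node id.
#' @param name New label (unique among siblings).
#' @export
rename_storage_node <- function(db, node, name) {
  authz(db, task = "f", action = "write")
  db_update(db, "storage", node, list(storage_name = name))
  invisible(node)
}

#' Move (re-parent) a storage node
#'
#' Permitted only when the re-rooted subtree still respects the five-level
#' depth bound and no cycle would arise.
#'
#' @param db A database handle.
#' @param node Node id.
#' @param new_parent New parent id, or `NULL` to make the node a root.
#' @export
move_storage_node <- function(db, node, new_parent = NULL) {
  authz(db, task = "f", action = "write")
  storage_node(db, node)
  subtree_depth <- function(n) {
    ch <- node_children(db, n)
    if (nrow(ch) == 0L) 1L else 1L + max(vapply(ch$storage_id, subtree_depth, 0L))
  }
  if (!is.null(new_parent)) {
    if (node %in% node_path_ids(db, new_parent))
      stop_genolims("cannot move a node into its own subtree", "genolims_tree_cycle")
    if (node_level(db, new_parent) + subtree_depth(node) > MAX_STORAGE_DEPTH)
      stop_genolims("move would exceed the five-level depth bound",
                    "genolims_depth_exceeded")
  }
  db_update(db, "storage", node, list(parent_id = new_parent))
  invisible(node)
}

item_arg <- function(item_type, item_id) {
  item_type <- match.arg(item_type, c("sample", "dna"))
  list(type = item_type, id = as.integer(item_id))
}

check_item_exists <- function(db, it) {
  ok <- if (it$type == "sample") !is.null(db_get(db, "samples", it$id))
  else nrow(dbGetQuery(db$con,
    "SELECT 1 FROM dna_extraction WHERE dna_id = ? LIMIT 1",
    params = list(it$id))) > 0L
  if (!ok) stop_genolims(sprintf("no %s with id %d", it$type, it$id),
                         "genolims_not_found")
}

open_placement <- function(db, it) {
  dbGetQuery(db$con,
    "SELECT * FROM storage_samples
      WHERE item_type = ? AND item_id = ? AND date_out IS NULL",
    params = list(it$type, it$id))
}

#' Place a sample or DNA item at a storage leaf
#'
#' Items can only sit at leaf nodes (a box or vessel), and an item has at
#' most one open placement; it must be checked out ([check_out_item()])
#' before being placed elsewhere, so the full movement history is
#' retained.
#'
#' @param db A database handle.
#' @param item_type `"sample"` or `"dna"`.
#' @param item_id Sample id or DNA (extraction group) id.
#' @param node Leaf node id.
#' @param date_in ISO date the item went in (defaults to today).
#' @param position_label Optional free-text position within the leaf.
#' @return The placement id, invisibly.
#' @export
place_item <- function(db, item_type, item_id, node,
                       date_in = format(Sys.Date()), position_label = NULL) {
  authz(db, task = "b", action = "write")
  it <- item_arg(item_type, item_id)
  check_item_exists(db, it)
  storage_node(db, node)
  if (!is_leaf(db, node))
    stop_genolims("not a leaf: items can only be placed at leaf nodes",
                  "genolims_not_leaf")
  if (nrow(open_placement(db, it)) > 0L)
    stop_genolims(sprintf("%s %d is already placed (check it out first)",
                          it$type, it$id), "genolims_already_placed")
  invisible(db_insert(db, "storage_samples", list(
    item_type = it$type, item_id = it$id, storage_id = node,
    date_in = date_in, position_label = position_label)))
}

#' Place many items at storage leaves in one batch
#'
#' Vectorised variant of [place_item()] with the same guarantees: every
#' target node must be a leaf and no item may already have an open
#' placement.
#'
#' @param db A database handle.
#' @param placements data.frame with columns `item_type`, `item_id`,
#'   `storage_id`, `date_in` and optionally `position_label`.
#' @return Integer vector of placement ids.
#' @export
place_items <- function(db, placements) {
  authz(db, task = "b", action = "write")
  if (nrow(placements) == 0L) return(integer(0))
  for (node in unique(placements$storage_id)) {
    storage_node(db, node)
    if (!is_leaf(db, node))
      stop_genolims(sprintf("not a leaf: node %d", node), "genolims_not_leaf")
  }
  key <- paste(placements$item_type, placements$item_id)
  if (anyDuplicated(key))
    stop_genolims("an item appears twice in the batch", "genolims_already_placed")
  open <- dbGetQuery(db$con,
    "SELECT item_type, item_id FROM storage_samples WHERE date_out IS NULL")
  if (any(key %in% paste(open$item_type, open$item_id)))
    stop_genolims("an item is already placed (check it out first)",
                  "genolims_already_placed")
  cols <- intersect(c("item_type", "item_id", "storage_id", "date_in",
                      "position_label"), names(placements))
  db_insert_many(db, "storage_samples", placements[, cols, drop = FALSE])
}

#' Check an item out of storage
#'
#' Closes the open placement by setting its out-date; the placement row is
#' kept as movement history.
#'
#' @inheritParams place_item
#' @param date_out ISO date (>= the placement's in-date).
#' @export
check_out_item <- function(db, item_type, item_id,
                           date_out = format(Sys.Date())) {
  authz(db, task = "b", action = "write")
  it <- item_arg(item_type, item_id)
  p <- open_placement(db, it)
  if (nrow(p) == 0L)
    stop_genolims(sprintf("%s %d is not in storage", it$type, it$id),
                  "genolims_not_placed")
  if (as.character(date_out) < p$date_in)
    stop_genolims("date_out must be on or after date_in", "genolims_invalid_value")
  db_update(db, "storage_samples", p$placement_id, list(date_out = date_out))
  invisible(p$placement_id)
}

#' Locate an item: its storage path from root to leaf
#'
#' @inheritParams place_item
#' @return data.frame of the nodes on the path (root first); its last row
#'   is the placement leaf.
#' @export
locate_item <- function(db, item_type, item_id) {
  authz(db, task = "c", action = "read")
  it <- item_arg(item_type, item_id)
  check_item_exists(db, it)
  p <- open_placement(db, it)
  if (nrow(p) == 0L)
    stop_genolims(sprintf("%s %d is not in storage", it$type, it$id),
                  "genolims_not_placed")
  ids <- node_path_ids(db, p$storage_id)
  path <- do.call(rbind, lapply(ids, function(i) storage_node(db, i)))
  path$level <- seq_along(ids)
  path
}

#' Render a storage path as text
#' @param path A path as returned by [locate_item()].
#' @export
format_storage_path <- function(path) {
  paste(path$storage_name, collapse = " / ")
}

#' List all items stored in a subtree
#'
#' Returns every item with an open placement at a leaf within the subtree
#' rooted at `node` (equal to the union over the node's children).
#'
#' @param db A database handle.
#' @param node Subtree root id.
#' @return data.frame of open placements within the subtree.
#' @export
list_subtree_items <- function(db, node) {
  authz(db, task = "c", action = "read")
  storage_node(db, node)
  ids <- node
  frontier <- node
  while (length(frontier)) {
    ch <- dbGetQuery(db$con, sprintf(
      "SELECT storage_id FROM storage WHERE parent_id IN (%s)",
      paste(frontier, collapse = ",")))$storage_id
    ids <- c(ids, ch)
    frontier <- ch
  }
  dbGetQuery(db$con, sprintf(
    "SELECT * FROM storage_samples
      WHERE date_out IS NULL AND storage_id IN (%s)
      ORDER BY placement_id", paste(ids, collapse = ",")))
}

#' The whole storage forest
#' @param db A database handle.
#' @return data.frame of all nodes with a computed `level` column.
#' @export
storage_tree <- function(db) {
  authz(db, task = "c", action = "read")
  tab <- db_table(db, "storage")
  if (nrow(tab) == 0L) { tab$level <- integer(0); return(tab) }
  lvl <- rep(NA_integer_, nrow(tab))
  lvl[is.na(tab$parent_id)] <- 1L
  while (anyNA(lvl)) {
    todo <- which(is.na(lvl))
    parent_lvl <- lvl[match(tab$parent_id[todo], tab$storage_id)]
    lvl[todo] <- parent_lvl + 1L
    if (all(is.na(parent_lvl))) break  # orphans; should not happen
  }
  tab$level <- lvl
  tab
}
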