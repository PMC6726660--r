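#' Ancestral reconstruction of a binary trait by parsimony
#'
#' Two-pass minimum-change (Fitch-style) parsimony for a binary character on
#' a rooted tree, generalised exactly to polytomies via unit-cost dynamic
#' programming over states (an up pass collecting subtree costs, a down pass
#' collecting outside costs). Per-node state sets contain every state that
#' occurs in at least one most-parsimonious labeling; `changes` is the
#' minimal number of state changes over the whole tree. Branch lengths are
#' ignored.
#'
#' Tips with state `?` are pruned with a warning before reconstruction. The
#' `resolved` column applies a stated convention, not an inference: a
#' singleton set resolves to its state; an ambiguous `{0,1}` node inherits
#' its parent's resolved state, and an ambiguous root resolves to presence
#' (1).
#'
#' @param tree a rooted [ape::phylo] tree (polytomies allowed).
#' @param traits a trait table as from [read_trait_table].
#' @param trait_name which trait to reconstruct.
#' @return an object of class `cx_recon`: the pruned tree, `changes`, and a
#'   `nodes` data frame (`node`, `label`, `state_set`, `resolved`); tip rows
#'   carry their observed state.
#' @export
fitch_reconstruct <- function(tree, traits, trait_name) {
  prep <- .prep_trait(tree, traits, trait_name)
  tree <- prep$tree
  states <- prep$states
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  total <- ntip + nnode
  INF <- .Machine$integer.max %/% 4L

  # up pass: cost[v, s] = min changes in subtree of v given state s at v
  cost <- matrix(INF, nrow = total, ncol = 2L)
  for (i in seq_len(ntip)) cost[i, states[tree$tip.label[i]] + 1L] <- 0L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(po[, 2L], po[, 1L])
  node_order <- unique(po[, 1L])  # postorder guarantees children first
  for (v in node_order) {
    acc <- c(0L, 0L)
    for (ch in children[[as.character(v)]]) {
      acc <- acc + c(min(cost[ch, 1L], cost[ch, 2L] + 1L),
                     min(cost[ch, 1L] + 1L, cost[ch, 2L]))
    }
    cost[v, ] <- acc
  }
  root <- ntip + 1L
  changes <- min(cost[root, ])

  # down pass: out[v, s] = min changes outside subtree of v given state s at v
  out <- matrix(INF, nrow = total, ncol = 2L)
  out[root, ] <- 0L
  parent_of <- integer(total)
  parent_of[po[, 2L]] <- po[, 1L]
  for (v in rev(node_order)) {
    kids <- children[[as.character(v)]]
    sub <- vapply(kids, function(ch) {
      c(min(cost[ch, 1L], cost[ch, 2L] + 1L),
        min(cost[ch, 1L] + 1L, cost[ch, 2L]))
    }, numeric(2L))  # 2 x k: contribution of each child to cost[v, s]
    for (ch in kids) {
      # cost at v from siblings only, per parent state
      sib1 <- cost[v, 1L] - sub[1L, which(kids == ch)]
      sib2 <- cost[v, 2L] - sub[2L, which(kids == ch)]
      out[ch, 1L] <- min(out[v, 1L] + sib1, out[v, 2L] + sib2 + 1L)
      out[ch, 2L] <- min(out[v, 1L] + sib1 + 1L, out[v, 2L] + sib2)
    }
  }

  in_mpr <- (cost + out) == changes
  set_str <- apply(in_mpr, 1L, function(r) {
    paste(c("0", "1")[r], collapse = "")
  })

  # resolution convention (preorder)
  resolved <- character(total)
  ord <- .preorder_nodes(tree)
  for (v in ord) {
    s <- set_str[v]
    resolved[v] <- if (nchar(s) == 1L) s else if (v == root) "1" else
      resolved[parent_of[v]]
  }

  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else
                rep("", nnode))
  nodes <- data.frame(node = seq_len(total), label = labels,
                      state_set = set_str, resolved = resolved,
                      is_tip = seq_len(total) <= ntip,
                      stringsAsFactors = FALSE)
  out_obj <- list(trait = trait_name, tree = tree, changes = changes,
                  nodes = nodes, method = "fitch")
  class(out_obj) <- "cx_recon"
  out_obj
}

.preorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")$edge
  root <- ape::Ntip(tree) + 1L
  c(root, rev(po[, 2L]))
}

.prep_trait <- function(tree, traits, trait_name) {
  stopifnot(inherits(tree, "phylo"))
  tt <- traits[traits$trait == trait_name, , drop = FALSE]
  if (nrow(tt) == 0L) stop("trait '", trait_name, "' absent from table",
                           call. = FALSE)
  states <- stats::setNames(tt$state, tt$taxon)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0L) {
    stop("no state for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unk <- tree$tip.label[states[tree$tip.label] == "?"]
  if (length(unk) == length(tree$tip.label)) {
    stop("all tips have unknown state", call. = FALSE)
  }
  if (length(unk) > 0L) {
    warning("pruning ", length(unk), " tip(s) with unknown state: ",
            paste(unk, collapse = ", "))
    tree <- ape::drop.tip(tree, unk, collapse.singles = TRUE)
  }
  st <- as.integer(states[tree$tip.label])
  names(st) <- tree$tip.label
  list(tree = tree, states = st)
}

#' @export
print.cx_recon <- function(x, ...) {
  cat(sprintf("<cx_recon> %s parsimony of '%s': %d change(s) on %d tips\n",
              x$method, x$trait, x$changes, ape::Ntip(x$tree)))
  invisible(x)
}

#' Dollo parsimony: single gain, minimal losses
#'
#' Reconstruction under the constraint that the trait arose exactly once.
#' The gain is placed on the branch subtending the most recent common
#' ancestor of all presence tips (the latest placement compatible with a
#' single origin, which also minimises losses); each maximal all-absent
#' subtree below it receives one loss. Tips with `?` are pruned with a
#' warning.
#'
#' @inheritParams fitch_reconstruct
#' @return an object of class `cx_recon` with `method = "dollo"`, the gain
#'   node, the loss nodes (roots of the lost subtrees) and `losses`, the
#'   loss count.
#' @export
dollo_reconstruct <- function(tree, traits, trait_name) {
  prep <- .prep_trait(tree, traits, trait_name)
  tree <- prep$tree
  states <- prep$states
  ntip <- ape::Ntip(tree)
  ones <- which(states[tree$tip.label] == 1L)
  if (length(ones) == 0L) {
    stop("no single-origin labeling: trait absent from every tip",
         call. = FALSE)
  }
  gain_node <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)

  # all-absent status per node (within the pruned tree)
  total <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  all_zero <- logical(total)
  all_zero[seq_len(ntip)] <- states[tree$tip.label] == 0L
  kids <- split(po[, 2L], po[, 1L])
  for (v in unique(po[, 1L])) {
    all_zero[v] <- all(all_zero[kids[[as.character(v)]]])
  }
  # losses: all-zero nodes inside the gain clade whose parent is not all-zero
  parent_of <- integer(total)
  parent_of[po[, 2L]] <- po[, 1L]
  in_clade <- .descendants(tree, gain_node)
  loss_nodes <- Filter(function(v) {
    all_zero[v] && v != gain_node &&
      (parent_of[v] == gain_node || !all_zero[parent_of[v]])
  }, in_clade)
  loss_nodes <- as.integer(loss_nodes)

  states_full <- integer(total)
  states_full[in_clade] <- 1L
  for (v in loss_nodes) states_full[.descendants(tree, v)] <- 0L
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else
                rep("", tree$Nnode))
  nodes <- data.frame(node = seq_len(total), label = labels,
                      state_set = as.character(states_full),
                      resolved = as.character(states_full),
                      is_tip = seq_len(total) <= ntip,
                      stringsAsFactors = FALSE)
  out <- list(trait = trait_name, tree = tree, changes = length(loss_nodes),
              losses = length(loss_nodes), gain_node = as.integer(gain_node),
              loss_nodes = loss_nodes, nodes = nodes, method = "dollo")
  class(out) <- "cx_recon"
  out
}

# node ids of a node and all its descendants
.descendants <- function(tree, node) {
  po <- ape::reorder.phylo(tree, "postorder")$edge
  total <- ape::Ntip(tree) + tree$Nnode
  keep <- logical(total)
  keep[node] <- TRUE
  for (i in rev(seq_len(nrow(po)))) {
    if (keep[po[i, 1L]]) keep[po[i, 2L]] <- TRUE
  }
  which(keep)
}

#' Tip labels descending from a node
#' @param tree a phylo tree.
#' @param node internal node id.
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  d <- .descendants(tree, node)
  tree$tip.label[d[d <= ape::Ntip(tree)]]
}
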