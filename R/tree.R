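# Population trees for the allele-frequency drift simulator.

#' Construct a population tree with per-branch drift
#'
#' A population tree is an edge list rooted at a single node. Each edge
#' carries a drift coefficient `d` in [0, 1): the child's allele frequency is
#' drawn from a Balding--Nichols beta distribution with mean equal to the
#' parent frequency and variance `d * f * (1 - f)`. Leaves are tagged with a
#' role (`outgroup`, `modern_west`, `modern_east`, or `ancient`); ancient
#' samples are attached to internal branches as additional leaves whose
#' drift is a fraction of the way down an existing branch.
#'
#' @param edges data.frame with columns `parent`, `child` (character labels)
#'   and `drift` (numeric in [0, 1)).
#' @param roles named character vector mapping every leaf label to one of
#'   `"outgroup"`, `"modern_west"`, `"modern_east"`, `"ancient"`.
#' @return an object of class `population_tree`.
#' @seealso [canonical_tree()] for the standard outgroup + east/west topology.
#' @export
population_tree <- function(edges, roles) {
  stopifnot(is.data.frame(edges), all(c("parent", "child", "drift") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (anyDuplicated(edges$child))
    stopf("each node may have only one parent (duplicated child label)")
  if (!is.numeric(edges$drift) || any(!is.finite(edges$drift)) ||
      any(edges$drift < 0) || any(edges$drift >= 1))
    stopf("every branch drift must lie in [0, 1)")
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1L)
    stopf("tree must have exactly one root, found %d: %s",
          length(roots), paste(roots, collapse = ", "))
  leaves <- setdiff(edges$child, edges$parent)
  roles <- roles[leaves]
  if (anyNA(roles) || !all(roles %in% c("outgroup", "modern_west", "modern_east", "ancient")))
    stopf("every leaf needs a role in {outgroup, modern_west, modern_east, ancient}")
  names(roles) <- leaves
  if (!any(roles == "outgroup")) stopf("tree needs at least one outgroup leaf")
  # topological order: parents before children
  ord <- character(0)
  pending <- roots
  while (length(pending)) {
    node <- pending[1L]; pending <- pending[-1L]
    ord <- c(ord, node)
    pending <- c(pending, edges$child[edges$parent == node])
  }
  structure(list(edges = edges, roles = roles, root = roots, order = ord,
                 leaves = leaves),
            class = "population_tree")
}

#' Canonical outgroup + east/west tree with an ancient attachment point
#'
#' The miniature demographic scenario the simulator is built around: an
#' outgroup (argali-like wild sheep) splits from the domestic lineage, which
#' then splits into a western and an eastern branch carrying the modern
#' breed populations. One ancient population ("ancient") is attached part of
#' the way down the western or eastern branch, emulating an early Anatolian
#' (west-affiliated) or central-Asian (east-affiliated) individual.
#'
#' @param d_outgroup drift on the outgroup branch.
#' @param d_stem drift from the root to the domestic ancestor.
#' @param d_west,d_east drift on the western / eastern branch below the
#'   domestic split.
#' @param ancient_side `"west"` or `"east"`: which branch the ancient
#'   population attaches to.
#' @param ancient_frac fraction of the branch's drift accumulated before the
#'   attachment point (0 = at the split, 1 = at the modern leaf).
#' @param d_ancient extra private drift on the ancient's own twig.
#' @return a [population_tree()].
#' @export
canonical_tree <- function(d_outgroup = 0.15, d_stem = 0.02,
                           d_west = 0.08, d_east = 0.08,
                           ancient_side = c("west", "east"),
                           ancient_frac = 0.5, d_ancient = 0.02) {
  ancient_side <- match.arg(ancient_side)
  stopifnot(ancient_frac >= 0, ancient_frac <= 1)
  d_branch <- if (ancient_side == "west") d_west else d_east
  d_attach <- d_branch * ancient_frac
  attach_parent <- sprintf("%s_mid", ancient_side)
  edges <- data.frame(
    parent = c("root", "root", "domestic", "domestic",
               "west_mid", "east_mid", attach_parent),
    child = c("outgroup", "domestic", "west_mid", "east_mid",
              "west", "east", "ancient"),
    drift = c(d_outgroup, d_stem,
              if (ancient_side == "west") d_attach else d_west * 0.5,
              if (ancient_side == "east") d_attach else d_east * 0.5,
              if (ancient_side == "west") d_west - d_attach else d_west * 0.5,
              if (ancient_side == "east") d_east - d_attach else d_east * 0.5,
              d_ancient),
    stringsAsFactors = FALSE)
  population_tree(edges, c(outgroup = "outgroup", west = "modern_west",
                           east = "modern_east", ancient = "ancient"))
}

#' @export
print.population_tree <- function(x, ...) {
  cat("Population tree:", length(x$leaves), "leaves, root =", x$root, "\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s  (drift %.3f)\n",
                x$edges$parent[i], x$edges$child[i], x$edges$drift[i]))
  cat("Roles:", paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = ", "), "\n")
  invisible(x)
}
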