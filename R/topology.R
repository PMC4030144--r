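#' The four sub-lexical slots of a sign form
#' @keywords internal
SLOT_ROLES <- c("location", "orientation", "handshape", "movement")

#' Describe a sign form
#'
#' A sign form is a lexical label plus exactly four sub-lexical units, one
#' per phonological parameter slot: location, orientation, handshape and
#' movement.
#'
#' @param label lexical identifier.
#' @param slots named character vector or list mapping each of the four
#'   slot roles to a sub-lexical unit id. Defaults to `<role>_<label>`.
#' @return An object of class `sign_form`.
#' @examples
#' sign_form("target")
#' @export
sign_form <- function(label, slots = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(slots)) {
    slots <- stats::setNames(paste0(SLOT_ROLES, "_", label), SLOT_ROLES)
  }
  slots <- unlist(slots)
  if (!setequal(names(slots), SLOT_ROLES)) {
    stop("slots must be named exactly ",
         paste(SLOT_ROLES, collapse = ", "), call. = FALSE)
  }
  slots <- slots[SLOT_ROLES]
  if (anyDuplicated(slots)) {
    stop("sub-lexical unit ids must be unique within a sign", call. = FALSE)
  }
  structure(list(label = label, slots = slots), class = "sign_form")
}

#' Describe a neighborhood
#'
#' A neighbor is a sign sharing exactly one sub-lexical unit with the
#' target (the sign-language convention, where neighborhood density equals
#' the shared unit's sub-lexical frequency). All neighbors of a target
#' share the same designated slot and are otherwise mutually disjoint.
#'
#' @param shared_slot which target slot the neighbors share
#'   ("location", "orientation", "handshape" or "movement").
#' @param n_neighbors number of neighbors (>= 0).
#' @return An object of class `neighbor_spec`.
#' @export
neighbor_spec <- function(shared_slot = "location", n_neighbors = 1L) {
  shared_slot <- match.arg(shared_slot, SLOT_ROLES)
  n_neighbors <- as.integer(n_neighbors)
  stopifnot(length(n_neighbors) == 1L, !is.na(n_neighbors), n_neighbors >= 0L)
  structure(list(shared_slot = shared_slot, n_neighbors = n_neighbors),
            class = "neighbor_spec")
}

#' Build a target-plus-neighbors network topology
#'
#' Constructs the unit inventory and connection structure for a target
#' sign and `n_neighbors` neighbors that all share one designated
#' sub-lexical slot with the target. Each neighbor's three non-shared
#' slots get fresh sub-lexical units, so the network has `4 + 3 k`
#' sub-lexical and `1 + k` lexical units. Every ordered pair of distinct
#' lexical units is a lateral inhibitory connection; lexical <->
#' sub-lexical connections follow membership and are bidirectional and
#' facilitatory.
#'
#' @param target a [sign_form()] (defaults to a canonical target).
#' @param spec a [neighbor_spec()] (defaults to no neighbors).
#' @return An object of class `sign_topology`: a list with a `units`
#'   data frame (`id`, `layer`, `role`), a `membership` list mapping each
#'   lexical id to its four sub-lexical ids, an `inhibition` data frame of
#'   ordered lexical pairs (`from`, `to`), and the shared slot/unit.
#' @examples
#' tp <- build_topology(spec = neighbor_spec("handshape", 1))
#' nrow(tp$units) # 7 sub-lexical + 2 lexical
#' @export
build_topology <- function(target = sign_form("target"),
                           spec = neighbor_spec(n_neighbors = 0L)) {
  stopifnot(inherits(target, "sign_form"), inherits(spec, "neighbor_spec"))
  k <- spec$n_neighbors
  shared_role <- spec$shared_slot
  shared_unit <- unname(target$slots[shared_role])

  sub_ids <- unname(target$slots)
  sub_roles <- SLOT_ROLES
  membership <- stats::setNames(list(unname(target$slots)), target$label)
  lex_ids <- target$label

  if (k > 0L) {
    for (i in seq_len(k)) {
      lab <- paste0("neighbor", i)
      own_roles <- setdiff(SLOT_ROLES, shared_role)
      own_ids <- paste0(own_roles, "_", lab)
      slots <- stats::setNames(character(4L), SLOT_ROLES)
      slots[shared_role] <- shared_unit
      slots[own_roles] <- own_ids
      sub_ids <- c(sub_ids, own_ids)
      sub_roles <- c(sub_roles, own_roles)
      membership[[lab]] <- unname(slots[SLOT_ROLES])
      lex_ids <- c(lex_ids, lab)
    }
  }

  units <- rbind(
    data.frame(id = sub_ids, layer = "sublexical", role = sub_roles,
               stringsAsFactors = FALSE),
    data.frame(id = lex_ids, layer = "lexical", role = "lexical",
               stringsAsFactors = FALSE)
  )
  pairs <- expand.grid(from = lex_ids, to = lex_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  rownames(pairs) <- NULL

  structure(list(
    units = units,
    membership = membership,
    inhibition = pairs,
    target = target$label,
    shared_slot = shared_role,
    shared_unit = shared_unit,
    n_neighbors = k
  ), class = "sign_topology")
}

#' Check the structural invariants of a topology
#'
#' Runs the full invariant suite on a topology without modifying it:
#' every lexical unit has exactly four sub-lexical members; all member ids
#' exist; neighbors share exactly one unit with the target and no units
#' with each other beyond that same shared unit; and the inhibition list
#' contains every ordered pair of distinct lexical units exactly once.
#'
#' @param topology a `sign_topology` (or a hand-built list with the same
#'   fields).
#' @return A data frame with one row per check: `check`, `pass`, `detail`.
#' @export
validate_topology <- function(topology) {
  units <- topology$units
  sub_ids <- units$id[units$layer == "sublexical"]
  lex_ids <- units$id[units$layer == "lexical"]
  mem <- topology$membership
  target <- topology$target

  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  arity_ok <- all(vapply(mem, length, integer(1)) == 4L)
  add("membership_arity", isTRUE(arity_ok),
      if (!arity_ok) "a lexical unit does not have exactly 4 members" else "")

  known <- all(unlist(mem) %in% sub_ids) && setequal(names(mem), lex_ids)
  add("membership_ids", isTRUE(known),
      if (!known) "membership references unknown unit ids" else "")

  sharing_ok <- TRUE
  detail <- ""
  if (!is.null(mem[[target]])) {
    tgt <- mem[[target]]
    nbs <- mem[setdiff(names(mem), target)]
    for (nm in names(nbs)) {
      ov <- intersect(nbs[[nm]], tgt)
      if (length(ov) != 1L) {
        sharing_ok <- FALSE
        detail <- sprintf("%s shares %d units with the target", nm, length(ov))
      }
    }
    if (sharing_ok && length(nbs) > 1L) {
      shared <- intersect(nbs[[1L]], tgt)
      for (i in seq_along(nbs)) for (j in seq_along(nbs)) {
        if (i < j) {
          ov <- setdiff(intersect(nbs[[i]], nbs[[j]]), shared)
          if (length(ov) > 0L) {
            sharing_ok <- FALSE
            detail <- sprintf("%s and %s share non-target unit(s)",
                              names(nbs)[i], names(nbs)[j])
          }
        }
      }
    }
  } else {
    sharing_ok <- FALSE
    detail <- "target lexical unit missing from membership"
  }
  add("sharing_pattern", isTRUE(sharing_ok), detail)

  nl <- length(lex_ids)
  inh <- topology$inhibition
  key <- paste(inh$from, inh$to)
  want <- expand.grid(from = lex_ids, to = lex_ids, stringsAsFactors = FALSE)
  want <- want[want$from != want$to, , drop = FALSE]
  pairs_ok <- !anyDuplicated(key) &&
    setequal(key, paste(want$from, want$to)) &&
    nrow(inh) == nl * (nl - 1L)
  add("inhibition_pairs", isTRUE(pairs_ok),
      if (!pairs_ok) "inhibition list is not all ordered distinct pairs" else "")

  do.call(rbind, res)
}

#' @export
print.sign_topology <- function(x, ...) {
  cat(sprintf("<sign_topology> target '%s' + %d neighbor(s) sharing '%s'\n",
              x$target, x$n_neighbors, x$shared_slot))
  cat(sprintf("  %d sub-lexical + %d lexical units, %d inhibitory pairs\n",
              sum(x$units$layer == "sublexical"),
              sum(x$units$layer == "lexical"),
              nrow(x$inhibition)))
  invisible(x)
}

#' Write a topology to a JSON file
#'
#' @param topology a `sign_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    units = topology$units,
    membership = topology$membership,
    target = topology$target,
    shared_slot = topology$shared_slot,
    n_neighbors = topology$n_neighbors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a topology from a JSON file written by [write_topology_json()]
#'
#' The inhibition pair list is reconstructed from the lexical unit set
#' (every ordered pair of distinct lexical units).
#'
#' @param path JSON file path.
#' @return A `sign_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- as.data.frame(obj$units, stringsAsFactors = FALSE)
  lex_ids <- units$id[units$layer == "lexical"]
  pairs <- expand.grid(from = lex_ids, to = lex_ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  rownames(pairs) <- NULL
  mem <- lapply(obj$membership, unlist)
  topo <- structure(list(
    units = units, membership = mem, inhibition = pairs,
    target = obj$target, shared_slot = obj$shared_slot,
    shared_unit = if (obj$n_neighbors > 0L)
      intersect(mem[[obj$target]], unlist(mem[setdiff(names(mem), obj$target)]))[1L]
    else unname(mem[[obj$target]][match(obj$shared_slot, SLOT_ROLES)]),
    n_neighbors = as.integer(obj$n_neighbors)
  ), class = "sign_topology")
  chk <- validate_topology(topo)
  if (!all(chk$pass)) {
    stop("invalid topology in ", path, ": ",
         paste(chk$check[!chk$pass], collapse = ", "), call. = FALSE)
  }
  topo
}
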