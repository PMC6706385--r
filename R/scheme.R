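#' Gating scheme of the resurgent sodium channel model
#'
#' The state graph is a deactivation-coupled inactivation ladder with a
#' resurgent branch. The upper row is the activation pathway: closed
#' states C1..Cn with statistical multipliers (n-1):..:1 on the
#' alpha/beta steps, opening into O1 via gamma/delta. Each closed state
#' has an inactivated partner IC1..ICn (vertical c_on/c_off), the open
#' state has its inactivated partner I1 (vertical o_on/o_off), and the
#' inactivated row is connected horizontally by the same alpha/beta/
#' gamma/delta laws. Because the open-state inactivation equilibrium
#' (o_on/o_off) is far stronger than the closed-state one (c_on/c_off),
#' recovery from inactivation proceeds by deactivation along the
#' inactivated row and unbinding at the resting end -- channels must
#' deactivate to recover -- while the steady open probability during a
#' maintained depolarization collapses to ~o_off/o_on.
#'
#' The resurgent branch hangs off the open states: O1-O2 (o1o2/o2o1),
#' O2-I2 (o2i2/i2o2) and I1-I2 (i1i2/i2i1). Channels driven through
#' O2 into I2 by a strong depolarization reopen through O2 on
#' repolarization, producing the resurgent current. Conducting states
#' are O1 and O2.
#'
#' @param n_closed number of closed states in the activation chain
#' @return an object of class \code{gating_scheme} with elements
#'   \code{states}, \code{transitions} (data.frame: from, to, rate,
#'   mult) and \code{conducting}
#' @export
gating_scheme <- function(n_closed = 4L) {
  n_closed <- as.integer(n_closed)
  stopifnot(n_closed >= 2L)
  closed <- paste0("C", seq_len(n_closed))
  iclosed <- paste0("IC", seq_len(n_closed))
  states <- c(closed, "O1", iclosed, "I1", "O2", "I2")
  tr <- list()
  add <- function(from, to, rate, mult = 1) {
    tr[[length(tr) + 1L]] <<- data.frame(from = from, to = to,
                                         rate = rate, mult = mult)
  }
  # activation row and its mirrored inactivated row
  for (i in seq_len(n_closed - 1L)) {
    add(closed[i], closed[i + 1L], "alpha", n_closed - i)
    add(closed[i + 1L], closed[i], "beta", i)
    add(iclosed[i], iclosed[i + 1L], "alpha", n_closed - i)
    add(iclosed[i + 1L], iclosed[i], "beta", i)
  }
  add(closed[n_closed], "O1", "gamma")
  add("O1", closed[n_closed], "delta")
  add(iclosed[n_closed], "I1", "gamma")
  add("I1", iclosed[n_closed], "delta")
  # vertical inactivation steps
  for (i in seq_len(n_closed)) {
    add(closed[i], iclosed[i], "c_on")
    add(iclosed[i], closed[i], "c_off")
  }
  add("O1", "I1", "o_on")
  add("I1", "O1", "o_off")
  # resurgent branch
  add("O1", "O2", "o1o2")
  add("O2", "O1", "o2o1")
  add("O2", "I2", "o2i2")
  add("I2", "O2", "i2o2")
  add("I1", "I2", "i1i2")
  add("I2", "I1", "i2i1")
  scheme <- structure(list(states = states,
                           transitions = do.call(rbind, tr),
                           conducting = c("O1", "O2")),
                      class = "gating_scheme")
  validate_scheme(scheme)
  scheme
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat(sprintf("gating scheme: %d states (%s), conducting: %s\n",
              length(x$states), paste(x$states, collapse = ", "),
              paste(x$conducting, collapse = ", ")))
  cat(sprintf("  %d directed transitions\n", nrow(x$transitions)))
  invisible(x)
}

validate_scheme <- function(scheme) {
  tr <- scheme$transitions
  stopifnot(all(tr$from %in% scheme$states), all(tr$to %in% scheme$states),
            all(tr$mult > 0), length(scheme$conducting) >= 1L,
            all(scheme$conducting %in% scheme$states))
  # every edge must have its reverse
  key <- paste(tr$from, tr$to)
  rkey <- paste(tr$to, tr$from)
  if (!all(rkey %in% key)) {
    stop("gating scheme is not reversible: missing reverse edges for ",
         paste(setdiff(rkey, key), collapse = "; "))
  }
  # connectivity by breadth-first search
  adj <- split(tr$to, tr$from)
  seen <- scheme$states[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (!setequal(seen, scheme$states)) {
    stop("gating scheme graph is not connected")
  }
  invisible(scheme)
}

#' Serialize a gating scheme to / from a YAML edge list
#'
#' @param scheme a [gating_scheme()]
#' @param path file path
#' @export
write_gating_scheme <- function(scheme, path) {
  tr <- scheme$transitions
  doc <- list(states = as.list(scheme$states),
              conducting = as.list(scheme$conducting),
              transitions = lapply(seq_len(nrow(tr)), function(i) {
                list(from = tr$from[i], to = tr$to[i],
                     rate = tr$rate[i], mult = tr$mult[i])
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_gating_scheme
#' @export
read_gating_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  tr <- do.call(rbind, lapply(doc$transitions, function(e) {
    data.frame(from = e$from, to = e$to, rate = e$rate,
               mult = as.numeric(e$mult))
  }))
  scheme <- structure(list(states = unlist(doc$states),
                           transitions = tr,
                           conducting = unlist(doc$conducting)),
                      class = "gating_scheme")
  validate_scheme(scheme)
  scheme
}

#' Report thermodynamic cycle imbalance of a scheme
#'
#' The rate table is taken verbatim and microscopic reversibility is not
#' enforced. For each elementary square / cycle of the state graph this
#' diagnostic computes the log-ratio of the clockwise to the
#' counter-clockwise rate product at a given voltage and temperature; a
#' non-zero value means the cycle is thermodynamically unbalanced
#' (steady-state probability flux circulates), which is accepted as part
#' of the published parameterization.
#'
#' @param scheme a [gating_scheme()]
#' @param params a [channel_params()]
#' @param V membrane potential (mV)
#' @param T temperature (degrees C)
#' @return named numeric vector of cycle log-imbalances
#' @export
cycle_imbalance <- function(scheme, params, V = 0, T = 25) {
  tr <- scheme$transitions
  r <- evaluate_rates(params, V, T)
  rate_of <- function(from, to) {
    i <- which(tr$from == from & tr$to == to)
    if (!length(i)) return(NA_real_)
    sum(tr$mult[i] * r[tr$rate[i]])
  }
  cycles <- find_cycles(scheme)
  out <- vapply(cycles, function(cyc) {
    fwd <- bwd <- 0
    for (i in seq_along(cyc)) {
      j <- if (i == length(cyc)) 1L else i + 1L
      fwd <- fwd + log(rate_of(cyc[i], cyc[j]))
      bwd <- bwd + log(rate_of(cyc[j], cyc[i]))
    }
    fwd - bwd
  }, numeric(1L))
  names(out) <- vapply(cycles, paste, character(1L), collapse = "-")
  out
}

# enumerate a fundamental cycle basis via a spanning tree
find_cycles <- function(scheme) {
  tr <- scheme$transitions
  edges <- unique(tr[, c("from", "to")])
  und <- unique(t(apply(edges, 1L, sort)))
  parent <- stats::setNames(rep(NA_character_, length(scheme$states)),
                            scheme$states)
  seen <- scheme$states[1L]
  tree <- character(0)
  frontier <- seen
  while (length(frontier)) {
    nf <- character(0)
    for (u in frontier) {
      nbr <- c(und[und[, 1L] == u, 2L], und[und[, 2L] == u, 1L])
      for (v in setdiff(nbr, seen)) {
        parent[v] <- u
        seen <- c(seen, v)
        nf <- c(nf, v)
        tree <- c(tree, paste(sort(c(u, v)), collapse = "|"))
      }
    }
    frontier <- nf
  }
  path_to_root <- function(v) {
    p <- v
    while (!is.na(parent[v])) {
      v <- parent[v]
      p <- c(p, v)
    }
    p
  }
  cycles <- list()
  for (i in seq_len(nrow(und))) {
    k <- paste(sort(und[i, ]), collapse = "|")
    if (k %in% tree) next
    pu <- path_to_root(und[i, 1L])
    pv <- path_to_root(und[i, 2L])
    common <- intersect(pu, pv)
    anc <- common[1L]
    cyc <- c(pu[seq_len(match(anc, pu))],
             rev(pv[seq_len(match(anc, pv) - 1L)]))
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}
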