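# A compact SMARTS-subset engine for substructure matching. Supports what the
# packaged ionization-site table and tautomer blacklist need: element and
# aromatic primitives, #n, charge, H/X/D/R counts, a/A, '*', negation '!',
# conjunction ';' '&', disjunction ',', bond primitives - = # : ~ and the
# default single-or-aromatic bond, branches and ring closures. No recursive
# SMARTS; site tables express exclusions as separate patterns instead.

#' Parse a SMARTS pattern
#' @param smarts pattern string
#' @return object of class `smarts_pattern`
#' @export
parse_smarts <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  n <- length(chars)
  atoms <- list()   # each: list of OR-groups, each a list of primitives
  bonds <- list()   # list(a1, a2, sym)
  ring_open <- list()
  prev <- 0L; pend <- ""; stack <- integer(0)
  i <- 1L

  add_atom <- function(tests) { atoms[[length(atoms) + 1L]] <<- tests; length(atoms) }
  add_bond <- function(a1, a2, sym) bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, sym = sym)

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") { prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L; next }
    if (ch %in% c("-", "=", "#", ":", "~")) {
      # '#' can open an atomic-number primitive only inside brackets
      pend <- ch; i <- i + 1L; next
    }
    if (grepl("[0-9]", ch)) {
      if (!is.null(ring_open[[ch]])) {
        op <- ring_open[[ch]]
        add_bond(op$atom, prev, if (nzchar(pend)) pend else op$sym)
        ring_open[[ch]] <- NULL
      } else ring_open[[ch]] <- list(atom = prev, sym = pend)
      pend <- ""; i <- i + 1L; next
    }
    if (ch == "[") {
      close <- i
      depth <- 0L
      repeat {
        close <- close + 1L
        if (close > n) stop("unterminated bracket in SMARTS: ", smarts)
        if (chars[close] == "]") break
      }
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      idx <- add_atom(parse_smarts_atom(body, smarts))
      if (prev != 0L) add_bond(prev, idx, pend)
      prev <- idx; pend <- ""; i <- close + 1L; next
    }
    # bare atom
    el <- NULL
    if (i < n && paste0(ch, chars[i + 1L]) %in% TWO_LETTER) {
      el <- paste0(ch, chars[i + 1L]); i <- i + 2L
      prim <- list(list(kind = "element", value = el, aromatic = FALSE, neg = FALSE))
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      el <- ch; i <- i + 1L
      prim <- list(list(kind = "element", value = el, aromatic = FALSE, neg = FALSE))
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      el <- toupper(ch); i <- i + 1L
      prim <- list(list(kind = "element", value = el, aromatic = TRUE, neg = FALSE))
    } else if (ch == "*") {
      i <- i + 1L
      prim <- list(list(kind = "any", neg = FALSE))
    } else if (ch == "a") {
      i <- i + 1L
      prim <- list(list(kind = "arom", value = TRUE, neg = FALSE))
    } else if (ch == "A") {
      i <- i + 1L
      prim <- list(list(kind = "arom", value = FALSE, neg = FALSE))
    } else stop(sprintf("unexpected '%s' in SMARTS: %s", ch, smarts))
    idx <- add_atom(list(list(prim)))  # one OR-group, one alternative
    if (prev != 0L) add_bond(prev, idx, pend)
    prev <- idx; pend <- ""
  }
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts),
            class = "smarts_pattern")
}

# Bracket body -> list of AND-groups (';'), each a list of OR-alternatives
# (','), each a list of primitives ('&'-joined, each possibly negated).
parse_smarts_atom <- function(body, smarts) {
  and_groups <- strsplit(body, ";", fixed = TRUE)[[1]]
  lapply(and_groups, function(grp) {
    alts <- strsplit(grp, ",", fixed = TRUE)[[1]]
    lapply(alts, function(alt) {
      parts <- strsplit(alt, "&", fixed = TRUE)[[1]]
      prims <- list()
      for (part in parts) {
        j <- 1L
        cs <- strsplit(part, "")[[1]]
        while (j <= length(cs)) {
          neg <- FALSE
          if (cs[j] == "!") { neg <- TRUE; j <- j + 1L }
          rest <- paste0(cs[j:length(cs)], collapse = "")
          m <- regmatches(rest, regexec(
            "^(#[0-9]+|Cl|Br|[A-Z][a-z]?|[bcnops]|\\*|H[0-9]?|X[0-9]|D[0-9]|R[0-9]?|\\+[0-9]?|-[0-9]?|@{1,2})", rest))[[1]]
          if (!length(m)) stop("cannot parse SMARTS atom primitive '", rest,
                               "' in: ", smarts)
          tok <- m[2]
          prim <- smarts_primitive(tok)
          prim$neg <- neg
          prims[[length(prims) + 1L]] <- prim
          j <- j + nchar(tok)
        }
      }
      prims
    })
  })
}

smarts_primitive <- function(tok) {
  if (grepl("^#", tok)) return(list(kind = "z", value = as.integer(substring(tok, 2))))
  if (tok == "*") return(list(kind = "any"))
  if (tok == "a") return(list(kind = "arom", value = TRUE))
  if (tok == "A") return(list(kind = "arom", value = FALSE))
  if (grepl("^H", tok)) {
    k <- if (tok == "H") 1L else as.integer(substring(tok, 2))
    return(list(kind = "hcount", value = k))
  }
  if (grepl("^X", tok)) return(list(kind = "conn", value = as.integer(substring(tok, 2))))
  if (grepl("^D", tok)) return(list(kind = "degree", value = as.integer(substring(tok, 2))))
  if (grepl("^R", tok)) {
    k <- if (tok == "R") -1L else as.integer(substring(tok, 2))  # -1 = any ring
    return(list(kind = "ring", value = k))
  }
  if (grepl("^\\+", tok)) {
    k <- if (tok == "+") 1L else as.integer(substring(tok, 2))
    return(list(kind = "charge", value = k))
  }
  if (grepl("^-", tok)) {
    k <- if (tok == "-") -1L else -as.integer(substring(tok, 2))
    return(list(kind = "charge", value = k))
  }
  if (tok %in% c("@", "@@")) return(list(kind = "any"))  # chirality ignored
  if (tok %in% c("b", "c", "n", "o", "p", "s"))
    return(list(kind = "element", value = toupper(tok), aromatic = TRUE))
  list(kind = "element", value = tok, aromatic = FALSE)
}

# Evaluate an atom-test structure against graph atom a (with precomputed ctx).
smarts_atom_ok <- function(tests, ctx, a) {
  for (grp in tests) {            # AND over groups
    grp_ok <- FALSE
    for (alt in grp) {            # OR over alternatives
      alt_ok <- TRUE
      for (p in alt) {            # AND over primitives
        val <- smarts_prim_ok(p, ctx, a)
        if (isTRUE(p$neg)) val <- !val
        if (!val) { alt_ok <- FALSE; break }
      }
      if (alt_ok) { grp_ok <- TRUE; break }
    }
    if (!grp_ok) return(FALSE)
  }
  TRUE
}

smarts_prim_ok <- function(p, ctx, a) {
  switch(p$kind,
    any = TRUE,
    element = {
      ok <- ctx$element[a] == p$value
      if (ok && !is.null(p$aromatic)) {
        ok <- if (p$aromatic) ctx$aromatic[a] else !ctx$aromatic[a]
      }
      ok
    },
    z = atomic_number(ctx$element[a]) == p$value,
    arom = ctx$aromatic[a] == p$value,
    hcount = ctx$hcount[a] == p$value,
    conn = (ctx$degree[a] + ctx$hcount[a]) == p$value,
    degree = ctx$degree[a] == p$value,
    ring = if (p$value < 0L) ctx$inring[a] else
             (if (p$value == 0L) !ctx$inring[a] else ctx$inring[a]),
    charge = ctx$charge[a] == p$value,
    FALSE)
}

smarts_bond_ok <- function(sym, g, k) {
  o <- g$bonds$order[k]; ar <- g$bonds$arom[k]
  switch(ifelse(nzchar(sym), sym, "default"),
    default = (o == 1L) || ar,
    "-" = o == 1L && !ar,
    "=" = o == 2L && !ar,
    "#" = o == 3L,
    ":" = ar,
    "~" = TRUE,
    FALSE)
}

#' Find all matches of a SMARTS pattern
#'
#' @param g mol_graph
#' @param pattern `smarts_pattern` or pattern string
#' @param unique_sets drop matches that map to an already-seen atom set.
#' @return list of integer vectors; element i gives the graph atom matched by
#'   pattern atom i.
#' @export
smarts_match_all <- function(g, pattern, unique_sets = TRUE) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  np <- length(pattern$atoms)
  if (np == 0L) return(list())
  ng <- n_atoms(g)
  ctx <- list(element = g$atoms$element, charge = g$atoms$charge,
              hcount = g$atoms$hcount, aromatic = g$atoms$aromatic,
              degree = lengths(adjacency(g)), inring = ring_membership(g))

  # pattern adjacency
  padj <- vector("list", np)
  for (b in pattern$bonds) {
    padj[[b$a1]] <- c(padj[[b$a1]], list(list(other = b$a2, sym = b$sym)))
    padj[[b$a2]] <- c(padj[[b$a2]], list(list(other = b$a1, sym = b$sym)))
  }
  # visit order: DFS from atom 1 (patterns are written connected)
  visit_order <- integer(0); seen <- rep(FALSE, np)
  dfs <- function(u) {
    seen[u] <<- TRUE; visit_order <<- c(visit_order, u)
    for (e in padj[[u]]) if (!seen[e$other]) dfs(e$other)
  }
  dfs(1L)
  if (length(visit_order) < np) visit_order <- c(visit_order, which(!seen))

  results <- list()
  assignment <- integer(np)
  extend <- function(pos) {
    if (pos > np) {
      results[[length(results) + 1L]] <<- assignment
      return(invisible(NULL))
    }
    pa <- visit_order[pos]
    # graph candidates: neighbors of an already-mapped pattern neighbor, else all
    anchored <- Filter(function(e) assignment[e$other] != 0L, padj[[pa]])
    cands <- if (length(anchored)) {
      ga <- assignment[anchored[[1]]$other]
      nbrs <- c(g$bonds$a2[g$bonds$a1 == ga], g$bonds$a1[g$bonds$a2 == ga])
      nbrs
    } else seq_len(ng)
    for (cand in cands) {
      if (cand %in% assignment[assignment != 0L]) next
      if (!smarts_atom_ok(pattern$atoms[[pa]], ctx, cand)) next
      ok <- TRUE
      for (e in padj[[pa]]) {
        gb <- assignment[e$other]
        if (gb == 0L) next
        k <- bond_index(g, cand, gb)
        if (k == 0L || !smarts_bond_ok(e$sym, g, k)) { ok <- FALSE; break }
      }
      if (!ok) next
      assignment[pa] <<- cand
      extend(pos + 1L)
      assignment[pa] <<- 0L
    }
  }
  extend(1L)
  if (unique_sets && length(results)) {
    keys <- vapply(results, function(m) paste(sort(m), collapse = ","), character(1))
    results <- results[!duplicated(keys)]
  }
  results
}

#' Test whether a molecule contains a substructure
#' @inheritParams smarts_match_all
#' @return logical
#' @export
smarts_has_match <- function(g, pattern) length(smarts_match_all(g, pattern)) > 0L
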