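# SMILES reader.
#
# Supports the common subset needed for drug-like molecules: organic-subset
# atoms, aromatic lowercase atoms, bracket atoms with isotope / chirality /
# hydrogen count / charge, single-double-triple and aromatic bonds, branches,
# ring-closure digits (including %nn), dots (fragments) and directional
# bonds for double-bond stereo. Parsed molecules are kekulized immediately;
# aromaticity is then re-perceived so that all downstream stages share one
# aromaticity model.

TWO_LETTER <- c("Cl", "Br")

#' Parse a SMILES string
#'
#' @param smiles SMILES string.
#' @return a [mol_graph()]
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles))
    stop("empty SMILES")
  s <- trimws(smiles)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  atoms <- list()      # each: list(element, charge, hcount, aromatic_in, isotope,
                       #            parity, bracket, explicit_h)
  bonds <- list()      # each: list(a1, a2, sym)  sym in - = # : / \ or "" (implicit)
  nbr_order <- list()  # chirality reference order per atom (0 = implicit H slot)
  ring_open <- list()  # digit -> list(atom, sym, slot)
  dirs <- list()       # directional bonds: list(u, v, sym) u written first

  prev <- 0L           # previous atom index (0 at start / after dot)
  pend_bond <- ""      # pending bond symbol
  stack <- integer(0)
  i <- 1L

  new_atom <- function(el, aromatic, charge = 0L, hcount = NA_integer_,
                       isotope = 0L, parity = 0L, bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, charge = charge,
      hcount = hcount, aromatic_in = aromatic, isotope = isotope,
      parity = parity, bracket = bracket)
    nbr_order[[length(atoms)]] <<- integer(0)
    length(atoms)
  }
  add_bond <- function(a1, a2, sym) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, sym = sym)
    if (sym %in% c("/", "\\")) dirs[[length(dirs) + 1L]] <<- list(u = a1, v = a2, sym = sym)
    nbr_order[[a1]] <<- c(nbr_order[[a1]], a2)
    nbr_order[[a2]] <<- c(nbr_order[[a2]], a1)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) { pend_bond <- ch; i <- i + 1L; next }
    if (ch == ".") { prev <- 0L; pend_bond <- ""; i <- i + 1L; next }
    if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("bad ring closure in SMILES: ", smiles)
        digit <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { digit <- ch; i <- i + 1L }
      if (prev == 0L) stop("ring closure with no open atom in SMILES: ", smiles)
      if (!is.null(ring_open[[digit]])) {
        op <- ring_open[[digit]]
        sym <- if (nzchar(pend_bond)) pend_bond else op$sym
        if (nzchar(op$sym) && nzchar(pend_bond) && op$sym != pend_bond &&
            !all(c(op$sym, pend_bond) %in% c("/", "\\")))
          stop("conflicting ring-bond orders in SMILES: ", smiles)
        bonds[[length(bonds) + 1L]] <- list(a1 = op$atom, a2 = prev, sym = sym)
        if (sym %in% c("/", "\\")) dirs[[length(dirs) + 1L]] <- list(u = op$atom, v = prev, sym = sym)
        # opening atom recorded a slot at digit position; fill it now
        nbr_order[[op$atom]][op$slot] <- prev
        nbr_order[[prev]] <- c(nbr_order[[prev]], op$atom)
        ring_open[[digit]] <- NULL
      } else {
        nbr_order[[prev]] <- c(nbr_order[[prev]], NA_integer_)
        ring_open[[digit]] <- list(atom = prev, sym = pend_bond,
                                   slot = length(nbr_order[[prev]]))
      }
      pend_bond <- ""
      next
    }
    if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (!length(close)) stop("unterminated bracket atom in SMILES: ", smiles)
      close <- close[1]
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- new_atom(at$element, at$aromatic, at$charge, at$hcount,
                      at$isotope, at$parity, bracket = TRUE)
      if (prev != 0L) add_bond(prev, idx, pend_bond)
      if (!is.na(at$hcount) && at$hcount > 0L && at$parity != 0L)
        nbr_order[[idx]] <- c(nbr_order[[idx]], 0L)
      prev <- idx; pend_bond <- ""
      i <- close + 1L
      next
    }
    # organic subset / aromatic atom
    el <- NULL; aromatic <- FALSE
    if (i < n && paste0(ch, chars[i + 1L]) %in% TWO_LETTER) {
      el <- paste0(ch, chars[i + 1L]); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      el <- ch; i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      el <- toupper(ch); aromatic <- TRUE; i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in SMILES: %s", ch, smiles))
    }
    idx <- new_atom(el, aromatic)
    if (prev != 0L) add_bond(prev, idx, pend_bond)
    prev <- idx; pend_bond <- ""
  }
  if (length(stack)) stop("unbalanced parenthesis in SMILES: ", smiles)
  open_digits <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_digits)) stop("unclosed ring bond in SMILES: ", smiles)

  build_graph_from_parse(atoms, bonds, nbr_order, dirs, smiles)
}

# body of a bracket atom, e.g. "C@H", "NH3+", "13CH", "O-", "nH"
parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?$", body))[[1]]
  if (!length(m)) stop("cannot parse bracket atom [", body, "] in SMILES: ", smiles)
  isotope <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  el <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  if (!el %in% names(PERIODIC$number))
    stop("unknown element [", body, "] in SMILES: ", smiles)
  parity <- if (m[4] == "@") 1L else if (m[4] == "@@") 2L else 0L
  hcount <- if (nzchar(m[5])) {
    if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  } else 0L
  chg <- m[6]
  charge <- if (!nzchar(chg)) 0L
  else if (chg %in% c("+", "-")) ifelse(chg == "+", 1L, -1L)
  else if (grepl("^\\++$", chg)) nchar(chg)
  else if (grepl("^-+$", chg)) -nchar(chg)
  else as.integer(chg)  # e.g. "+2", "-1"
  list(element = el, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount, isotope = isotope, parity = parity)
}

build_graph_from_parse <- function(atoms, bonds, nbr_order, dirs, smiles) {
  na <- length(atoms)
  if (na == 0L) stop("no atoms in SMILES: ", smiles)
  adf <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, function(a) if (is.na(a$hcount)) 0L else a$hcount, integer(1)),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic_in"),
    isotope = vapply(atoms, `[[`, integer(1), "isotope"),
    parity = vapply(atoms, `[[`, integer(1), "parity"),
    stringsAsFactors = FALSE
  )
  bracket <- vapply(atoms, `[[`, logical(1), "bracket")
  nb <- length(bonds)
  arom_in <- adf$aromatic
  bdf <- data.frame(
    a1 = vapply(bonds, `[[`, integer(1), "a1"),
    a2 = vapply(bonds, `[[`, integer(1), "a2"),
    order = vapply(bonds, function(b) switch(b$sym, "=" = 2L, "#" = 3L, 1L), integer(1)),
    arom = vapply(bonds, function(b) {
      (b$sym == ":") || (!nzchar(b$sym) || b$sym %in% c("/", "\\")) &&
        arom_in[b$a1] && arom_in[b$a2]
    }, logical(1)),
    stereo = rep("none", nb), sref1 = rep(0L, nb), sref2 = rep(0L, nb),
    stringsAsFactors = FALSE
  )
  if (any(is.na(bdf$a1)) || any(is.na(bdf$a2))) stop("bad bond in SMILES: ", smiles)

  g <- mol_graph(adf, bdf, nbr_order)
  g <- kekulize(g)

  # implicit hydrogens for non-bracket atoms
  osum <- bond_order_sums(g)
  for (i in seq_len(na)) {
    if (!bracket[i]) {
      g$atoms$hcount[i] <- implied_hcount(g$atoms$element[i], g$atoms$charge[i], osum[i])
    }
  }
  g <- apply_directional_bonds(g, dirs)
  g <- perceive_aromaticity(g)
  validate_valences(g, smiles)
  g
}

validate_valences <- function(g, smiles) {
  osum <- bond_order_sums(g) + g$atoms$hcount
  for (i in seq_len(n_atoms(g))) {
    el <- g$atoms$element[i]
    vals <- DEFAULT_VALENCES[[el]]
    if (is.null(vals)) next
    chg <- g$atoms$charge[i]
    adj <- 0L
    if (el %in% c("N", "P") && chg != 0) adj <- chg
    if (el %in% c("O", "S") && chg != 0) adj <- chg
    if (el == "C" && chg != 0) adj <- -abs(chg)
    if (el == "B" && chg < 0) adj <- 1L
    if (!any(osum[i] <= vals + adj))
      stop(sprintf("valence of %s atom %d (%g) exceeds allowed in SMILES: %s",
                   el, i, osum[i], smiles))
  }
  invisible(TRUE)
}

# Convert parsed directional (/ \) single bonds into cis/trans annotations on
# the adjacent double bonds. Convention: '/' written u->v means the bond
# ascends from u to v. For double bond a1=a2 with directional neighbors n1, n2:
# equal ascent direction (n->a for both ends) means same side (cis refs).
apply_directional_bonds <- function(g, dirs) {
  if (!length(dirs) || !nrow(g$bonds)) return(g)
  dirkey <- function(u, v) paste(u, v)
  dmap <- new.env(parent = emptyenv())
  for (d in dirs) {
    assign(dirkey(d$u, d$v), d$sym, envir = dmap)
  }
  get_dir <- function(nbr, a) {
    # +1 if ascending nbr -> a, 0 if no directional bond
    k1 <- dirkey(nbr, a); k2 <- dirkey(a, nbr)
    if (!is.null(s <- mget(k1, envir = dmap, ifnotfound = list(NULL))[[1]]))
      return(if (s == "/") 1L else -1L)
    if (!is.null(s <- mget(k2, envir = dmap, ifnotfound = list(NULL))[[1]]))
      return(if (s == "/") -1L else 1L)
    0L
  }
  nb <- adjacency(g)
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 2L || g$bonds$arom[k]) next
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    d1 <- 0L; n1 <- 0L
    for (x in setdiff(nb[[a1]], a2)) {
      dd <- get_dir(x, a1)
      if (dd != 0L) { d1 <- dd; n1 <- x; break }
    }
    d2 <- 0L; n2 <- 0L
    for (x in setdiff(nb[[a2]], a1)) {
      dd <- get_dir(x, a2)
      if (dd != 0L) { d2 <- dd; n2 <- x; break }
    }
    if (d1 != 0L && d2 != 0L) {
      g$bonds$stereo[k] <- if (d1 == d2) "cis" else "trans"
      g$bonds$sref1[k] <- n1
      g$bonds$sref2[k] <- n2
    }
  }
  g
}
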