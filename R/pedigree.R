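#' Simulate an isolate-style multigeneration pedigree
#'
#' Builds a pedigree descending from `n_founder_couples` founder couples.
#' Each couple has a Poisson(`mean_children`) number of children, truncated at
#' one child per couple so the pedigree stays connected (with
#' `mean_children = 0` no children are produced at all). Children of every
#' generation before the last marry a newly introduced, unrelated spouse
#' ("married-in" founder) and the resulting couples produce the next
#' generation. Households are full sibships: all children of one couple share
#' a household; founders get singleton households.
#'
#' @param n_founder_couples Number of founding couples (>= 1).
#' @param n_generations Number of descendant generations to simulate (>= 1).
#' @param mean_children Mean number of children per couple (Poisson rate).
#' @param seed Optional integer seed; a fixed seed reproduces the pedigree
#'   exactly.
#' @param children_per_couple Optional fixed child count overriding the
#'   Poisson model (useful for deterministic fixtures).
#'
#' @return A tibble with one row per individual and columns `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (`"male"`/`"female"`), `household`,
#'   `generation` (0 for the founding generation) and `founder`.
#' @export
#' @examples
#' ped <- simulate_pedigree(4, 2, mean_children = 3, seed = 1)
#' dplyr::count(ped, generation)
simulate_pedigree <- function(n_founder_couples, n_generations,
                              mean_children = 2.5, seed = NULL,
                              children_per_couple = NULL) {
  if (!is.numeric(n_founder_couples) || n_founder_couples < 1 ||
      !is.numeric(n_generations) || n_generations < 1) {
    abort("`n_founder_couples` and `n_generations` must be positive counts.",
          class = "mqtl_invalid_argument")
  }
  if (mean_children < 0) {
    abort("`mean_children` must be non-negative.",
          class = "mqtl_invalid_argument")
  }
  with_seed_if(seed, {
    rows <- list()
    n_id <- 0L
    new_id <- function() {
      n_id <<- n_id + 1L
      sprintf("I%05d", n_id)
    }
    n_hh <- 0L
    new_hh <- function() {
      n_hh <<- n_hh + 1L
      sprintf("H%05d", n_hh)
    }
    # founding couples
    couples <- vector("list", n_founder_couples)
    for (i in seq_len(n_founder_couples)) {
      f <- new_id(); m <- new_id()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = c(f, m), father = NA_character_, mother = NA_character_,
        sex = c("male", "female"), household = c(new_hh(), new_hh()),
        generation = 0L, founder = TRUE)
      couples[[i]] <- c(father = f, mother = m)
    }
    for (g in seq_len(n_generations)) {
      next_couples <- list()
      for (cp in couples) {
        k <- if (!is.null(children_per_couple)) {
          as.integer(children_per_couple)
        } else if (mean_children == 0) {
          0L
        } else {
          # zero-truncated Poisson keeps every couple connected
          k0 <- rpois(1, mean_children)
          while (k0 == 0L) k0 <- rpois(1, mean_children)
          k0
        }
        if (k == 0L) next
        hh <- new_hh()
        for (j in seq_len(k)) {
          cid <- new_id()
          csex <- if (runif(1) < 0.5) "male" else "female"
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = cid, father = cp[["father"]], mother = cp[["mother"]],
            sex = csex, household = hh, generation = g, founder = FALSE)
          if (g < n_generations) {
            sid <- new_id()
            ssex <- if (csex == "male") "female" else "male"
            rows[[length(rows) + 1L]] <- tibble::tibble(
              id = sid, father = NA_character_, mother = NA_character_,
              sex = ssex, household = new_hh(), generation = g,
              founder = TRUE)
            next_couples[[length(next_couples) + 1L]] <- c(
              father = if (csex == "male") cid else sid,
              mother = if (csex == "male") sid else cid)
          }
        }
      }
      couples <- next_couples
      if (length(couples) == 0L && g < n_generations) break
    }
    ped <- dplyr::bind_rows(rows)
    validate_pedigree(ped)
    ped
  })
}

#' Validate pedigree structure
#'
#' Checks the structural invariants a pedigree must satisfy before kinship
#' computation: parents present in the table, both parents present for every
#' non-founder, no individual its own ancestor (acyclic parent graph), and
#' full siblings sharing a household.
#'
#' @param ped Pedigree tibble as produced by [simulate_pedigree()].
#' @return `ped`, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "father", "mother", "sex", "household")
  if (!all(req %in% names(ped))) {
    abort(paste("pedigree must have columns:", paste(req, collapse = ", ")),
          class = "mqtl_invalid_argument")
  }
  if (anyDuplicated(ped$id)) {
    abort("duplicate individual ids in pedigree.", class = "mqtl_structural")
  }
  has_f <- !is.na(ped$father); has_m <- !is.na(ped$mother)
  if (any(has_f != has_m)) {
    abort("every non-founder must have both parents present.",
          class = "mqtl_structural")
  }
  pp <- c(ped$father[has_f], ped$mother[has_m])
  if (!all(pp %in% ped$id)) {
    abort("parental ids reference individuals missing from the pedigree.",
          class = "mqtl_structural")
  }
  pedigree_order(ped)  # errors on cycles
  # full siblings share a household
  kids <- ped[has_f, ]
  if (nrow(kids) > 0) {
    key <- paste(kids$father, kids$mother)
    n_hh <- tapply(kids$household, key, function(h) length(unique(h)))
    if (any(n_hh > 1)) {
      abort("full siblings must share a household id.",
            class = "mqtl_structural")
    }
  }
  invisible(ped)
}

# Topological order of individuals (parents before children).
# Errors with class mqtl_structural on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  depth <- rep(NA_integer_, n)
  depth[is.na(fi)] <- 0L
  for (it in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0L) break
    ready <- todo[!is.na(depth[fi[todo]]) & !is.na(depth[mi[todo]])]
    if (length(ready) == 0L) {
      abort("pedigree contains a cycle (an individual is its own ancestor).",
            class = "mqtl_structural")
    }
    depth[ready] <- pmax(depth[fi[ready]], depth[mi[ready]]) + 1L
  }
  order(depth)
}

#' Kinship matrix from a pedigree
#'
#' Computes kinship coefficients by the standard recursive tabular method,
#' processing individuals in generation order:
#' `phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2` for `j` already
#' processed, and `phi(i, i) = (1 + phi(father_i, mother_i)) / 2`. Founders
#' are unrelated and non-inbred, so their diagonal is 0.5. The matrix `2 *
#' phi` is the additive genetic relationship matrix used by the polygenic
#' model.
#'
#' @param ped Pedigree tibble (see [simulate_pedigree()]).
#' @return A symmetric numeric matrix of kinship coefficients with
#'   individual ids as dimnames.
#' @export
#' @examples
#' ped <- simulate_pedigree(1, 1, children_per_couple = 2, seed = 1)
#' kinship_from_pedigree(ped)  # sibling pairs at 0.25
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      prev <- seq_len(i - 1L)
      v <- 0.5 * (phi[fi[i], prev] + phi[mi[i], prev])
      phi[i, prev] <- v
      phi[prev, i] <- v
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
    }
  }
  phi
}

#' Household (sibship) incidence and covariance structure
#'
#' `household_design()` returns the 0/1 individual-by-household indicator
#' matrix Z; `household_matrix()` returns `H = Z Z'`, the 0/1 matrix whose
#' entry is 1 iff two individuals share a household (diagonal 1). `H` is
#' block-diagonal under household ordering and positive semi-definite.
#'
#' @param ped Pedigree tibble with `id` and `household` columns.
#' @return A numeric matrix (individuals in pedigree order).
#' @export
household_design <- function(ped) {
  hh <- factor(ped$household)
  Z <- matrix(0, nrow(ped), nlevels(hh),
              dimnames = list(ped$id, levels(hh)))
  Z[cbind(seq_len(nrow(ped)), as.integer(hh))] <- 1
  Z
}

#' @rdname household_design
#' @export
household_matrix <- function(ped) {
  Z <- household_design(ped)
  tcrossprod(Z)
}

#' Read and write FAM-style pedigree files
#'
#' Plain-text, whitespace-separated pedigree exchange format with columns
#' family id, individual id, father, mother, sex (1 = male, 2 = female) and,
#' in the sixth column (normally the phenotype slot), the household id.
#' Missing parents are coded `0`.
#'
#' @param ped Pedigree tibble.
#' @param path File path.
#' @param family_id Family id written in column 1.
#' @return `write_fam()` returns `path` invisibly; `read_fam()` returns a
#'   pedigree tibble (with `generation` recomputed from parental depth).
#' @export
write_fam <- function(ped, path, family_id = "FAM1") {
  validate_pedigree(ped)
  out <- tibble::tibble(
    fid = family_id,
    iid = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    household = ped$household)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("fid", "iid", "father", "mother",
                                             "sex", "household"),
                         col_types = "ccccic", progress = FALSE)
  ped <- tibble::tibble(
    id = raw$iid,
    father = ifelse(raw$father == "0", NA_character_, raw$father),
    mother = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex = ifelse(raw$sex == 1L, "male", "female"),
    household = raw$household)
  ped$founder <- is.na(ped$father)
  # recompute generation as parental depth
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  fi <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  depth <- rep(NA_integer_, nrow(ped))
  depth[is.na(fi)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    ready <- todo[!is.na(depth[fi[todo]]) & !is.na(depth[mi[todo]])]
    if (!length(ready)) abort("cyclic pedigree.", class = "mqtl_structural")
    depth[ready] <- pmax(depth[fi[ready]], depth[mi[ready]]) + 1L
  }
  # married-in founders sit at the generation of their first child minus one
  ped$generation <- depth
  validate_pedigree(ped)
  ped[c("id", "father", "mother", "sex", "household", "generation",
        "founder")]
}
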