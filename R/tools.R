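# Tool space: identities, the deterministic fitness ladder, and the
# recombination grammar (incremental advances within a lineage, crossovers
# between lineages).
#
# A tool is identified by (lineage, stage, level): lineage in {A,B,C,D},
# stage m >= 1, level n in {1,2,3}. Within a lineage, tools form a linear
# creation order 1.1, 1.2, 1.3, 2.1, 2.2, ... ; the "position" of a tool in
# that order is pos = 3*(stage-1) + level. Internally every tool is a single
# integer id = 4*(pos-1) + lineage_index, so toolkits are plain integer
# vectors and fitness is a ladder lookup. The user-facing representation is
# the label "A_2.1" (lineage, underscore, stage, dot, level), used in all
# CSV output.

LINEAGES <- c("A", "B", "C", "D")

# position in the within-lineage creation order
.pos <- function(stage, level) 3L * (as.integer(stage) - 1L) + as.integer(level)
.pos_stage <- function(pos) (pos - 1L) %/% 3L + 1L
.pos_level <- function(pos) (pos - 1L) %% 3L + 1L

.tool_id <- function(lin_idx, pos) 4L * (pos - 1L) + as.integer(lin_idx)
.id_pos <- function(id) (id - 1L) %/% 4L + 1L
.id_lin <- function(id) (id - 1L) %% 4L + 1L

# Fitness ladder over positions in the creation order, shared by all
# lineages: f(1.1) = 1, each incremental level multiplies by 1.05, each
# stage transition (crossover product) doubles the last level-3 fitness.
.ratchetr_env <- new.env(parent = emptyenv())

.fitness_ladder <- function(max_pos = 360L) {
  f <- .ratchetr_env$ladder
  if (!is.null(f) && length(f) >= max_pos) return(f)
  f <- numeric(max_pos)
  f[1L] <- 1
  for (p in 2:max_pos) {
    f[p] <- if ((p - 1L) %% 3L == 0L) 2 * f[p - 1L] else 1.05 * f[p - 1L]
  }
  .ratchetr_env$ladder <- f
  f
}

.id_fitness <- function(id) .fitness_ladder()[.id_pos(id)]

#' Fitness of a tool at a given stage and level
#'
#' Tool fitness is a pure function of position in the within-lineage
#' creation order (1.1, 1.2, 1.3, 2.1, ...), identical across lineages:
#' the first tool has fitness 1, each incremental level multiplies the
#' previous tool's fitness by 1.05, and each stage transition doubles the
#' fitness of the preceding level-3 tool. Hence `tool_fitness(1, 2) == 1.05`
#' and `tool_fitness(2, 1) == 2 * tool_fitness(1, 3)`.
#'
#' @param stage integer vector, stage index m >= 1.
#' @param level integer vector, level n in {1, 2, 3}.
#' @return numeric vector of fitness values.
#' @examples
#' tool_fitness(1, 1)  # 1
#' tool_fitness(2, 1)  # 2.205
#' @export
tool_fitness <- function(stage, level) {
  if (length(stage) == 0L || length(level) == 0L)
    stop("'stage' and 'level' must be non-empty")
  if (anyNA(stage) || anyNA(level) ||
      any(stage %% 1 != 0) || any(level %% 1 != 0))
    stop("'stage' and 'level' must be integer-valued")
  stage <- as.integer(stage)
  level <- as.integer(level)
  if (any(stage < 1L))
    stop("'stage' must be >= 1")
  if (any(!level %in% 1:3))
    stop("'level' must be in {1, 2, 3}")
  pos <- .pos(stage, level)
  .fitness_ladder(max(360L, max(pos)))[pos]
}

# label <-> id conversion ----------------------------------------------------

#' Convert tool labels to/from internal representation
#'
#' `parse_tools()` validates labels of the form `"A_2.1"` and returns a
#' data frame of tool fields; `tool_labels()` is used internally to render
#' ids. A toolkit anywhere in the public API is a character vector of such
#' labels.
#'
#' @param labels character vector of tool labels, e.g. `"B_1.3"`.
#' @return `parse_tools()`: data.frame with columns `label`, `lineage`,
#'   `stage`, `level`, `fitness`.
#' @examples
#' parse_tools(c("A_1.1", "D_3.2"))
#' @export
parse_tools <- function(labels) {
  ids <- .labels_to_ids(labels)
  data.frame(
    label = as.character(labels),
    lineage = LINEAGES[.id_lin(ids)],
    stage = .pos_stage(.id_pos(ids)),
    level = .pos_level(.id_pos(ids)),
    fitness = .id_fitness(ids),
    stringsAsFactors = FALSE
  )
}

.labels_to_ids <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))  # already ids
  ok <- grepl("^[ABCD]_[0-9]+\\.[123]$", labels)
  if (!all(ok))
    stop("malformed tool label(s): ", paste(labels[!ok], collapse = ", "))
  lin <- match(substr(labels, 1L, 1L), LINEAGES)
  rest <- substring(labels, 3L)
  stage <- as.integer(sub("\\..*$", "", rest))
  level <- as.integer(sub("^.*\\.", "", rest))
  if (any(stage < 1L)) stop("tool stage must be >= 1")
  .tool_id(lin, .pos(stage, level))
}

.ids_to_labels <- function(ids) {
  if (length(ids) == 0L) return(character(0))
  pos <- .id_pos(ids)
  paste0(LINEAGES[.id_lin(ids)], "_", .pos_stage(pos), ".", .pos_level(pos))
}

#' Fitness of tools given by label
#'
#' @param toolkit character vector of tool labels (see [parse_tools()]).
#' @return numeric vector of fitness values.
#' @export
toolkit_fitness <- function(toolkit) .id_fitness(.labels_to_ids(toolkit))

# recombination --------------------------------------------------------------

# Core grammar on integer ids. Returns the created tool id, or NA_integer_
# when the pair matches no recipe. `init_lin` is the lineage index of the
# tool contributed by the initiating agent; it only matters for crossovers,
# which place the new tool in the initiator's lineage.
.recombine_ids <- function(id_a, id_b, init_lin) {
  pa <- .id_pos(id_a); la <- .id_lin(id_a)
  pb <- .id_pos(id_b); lb <- .id_lin(id_b)
  if (la == lb) {
    # incremental: the two tools must be the two immediate predecessors of
    # the target in the linear creation order, and the target must not open
    # a new stage (stage transitions require a crossover).
    if (abs(pa - pb) == 1L) {
      tgt <- max(pa, pb) + 1L
      if ((tgt - 1L) %% 3L != 0L) return(.tool_id(la, tgt))
    }
    return(NA_integer_)
  }
  # crossover: two level-3 tools of the same stage, different lineages
  if (pa == pb && pa %% 3L == 0L) return(.tool_id(init_lin, pa + 1L))
  NA_integer_
}

#' Attempt to recombine two tools
#'
#' Applies the recombination grammar to one tool from each member of a dyad.
#' Two modes exist: an *incremental* advance combines the two immediate
#' predecessors of a target tool in one lineage's creation order (so
#' `A_1.1 + A_1.2 -> A_1.3`, and `A_1.3 + A_2.1 -> A_2.2`); a *crossover*
#' combines two level-3 tools of the same stage from different lineages and
#' produces the first tool of the next stage, placed in the lineage of the
#' tool contributed by the initiating agent (`A_1.3 + B_1.3 -> A_2.1` when
#' the initiator contributed the A tool, `B_2.1` when roles are inverted).
#' Any other pair produces nothing; a stage-opening tool can never arise
#' from an incremental recipe.
#'
#' @param tool_a label of the tool contributed by the initiating agent.
#' @param tool_b label of the tool contributed by the partner.
#' @param initiator lineage of the initiating agent's contribution; defaults
#'   to the lineage of `tool_a`.
#' @return list with elements `created` (tool label, or `NA` if no recipe
#'   matched) and `kind` (`"incremental"`, `"crossover"` or `"none"`).
#' @examples
#' recombine("A_1.3", "B_1.3")                   # crossover -> A_2.1
#' recombine("A_1.3", "B_1.3", initiator = "B")  # -> B_2.1
#' recombine("A_1.1", "A_1.2")                   # incremental -> A_1.3
#' @export
recombine <- function(tool_a, tool_b, initiator = NULL) {
  id_a <- .labels_to_ids(tool_a)
  id_b <- .labels_to_ids(tool_b)
  if (length(id_a) != 1L || length(id_b) != 1L)
    stop("'tool_a' and 'tool_b' must be single tools")
  init_lin <- if (is.null(initiator)) .id_lin(id_a) else match(initiator, LINEAGES)
  if (is.na(init_lin)) stop("'initiator' must be one of ", paste(LINEAGES, collapse = ", "))
  out <- .recombine_ids(id_a, id_b, init_lin)
  if (is.na(out)) {
    list(created = NA_character_, kind = "none")
  } else {
    kind <- if (.pos_level(.id_pos(out)) == 1L) "crossover" else "incremental"
    list(created = .ids_to_labels(out), kind = kind)
  }
}

#' The initial tool endowment
#'
#' Every agent starts with the same eight tools: levels 1.1 and 1.2 of each
#' of the four lineages, with baseline fitness 1 and 1.05. These are the
#' only two levels compatible with the incremental recipe reaching 1.3.
#'
#' @return character vector of 8 tool labels.
#' @examples
#' initial_toolkit()
#' @export
initial_toolkit <- function() .ids_to_labels(.initial_ids())

.initial_ids <- function() {
  as.integer(vapply(1:4, function(l) c(.tool_id(l, 1L), .tool_id(l, 2L)), integer(2)))
}
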