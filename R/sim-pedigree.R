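#' Build a multi-generation mating pedigree
#'
#' Founders (generation 0) are `nFoundersMale` males and `nFoundersFemale`
#' females.  For each subsequent generation, a fixed number of dams and sires
#' is drawn from the previous generation (all founder females/males for
#' generation 1), each dam mates with exactly one sire chosen uniformly among
#' that generation's sires, and litter sizes are Poisson around
#' `progenyPerFemale`, truncated to at least one.  Progeny sexes are assigned
#' independently with probability 1/2.
#'
#' @param config a [simConfig()].
#' @return `data.frame` with columns `id`, `sire`, `dam` (NA for founders),
#'   `sex` (`"male"`/`"female"`) and `generation` (0 = founders), ordered so
#'   that parents precede offspring.
#' @examples
#' set.seed(1)
#' ped <- buildPedigree(simConfig(generations = 1))
#' table(ped$generation)
#' @export
buildPedigree <- function(config) {
  nm <- config$nFoundersMale
  nf <- config$nFoundersFemale
  id <- paste0("ind", seq_len(nm + nf))
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = rep(c("male", "female"), c(nm, nf)),
                    generation = 0L, stringsAsFactors = FALSE)
  nextId <- nm + nf + 1L
  for (g in seq_len(config$generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == "male"]
    females <- prev$id[prev$sex == "female"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " has no available parents of both sexes")
    nDams <- if (g == 1L) length(females) else
      min(config$damsPerGeneration, length(females))
    nSires <- if (g == 1L) length(males) else
      min(config$siresPerGeneration, length(males))
    dams <- if (length(females) == 1L) females else
      sample(females, nDams)
    sires <- if (length(males) == 1L) males else sample(males, nSires)
    mate <- if (length(sires) == 1L) rep(sires, nDams) else
      sample(sires, nDams, replace = TRUE)
    litters <- pmax(1L, rpois(nDams, config$progenyPerFemale))
    tot <- sum(litters)
    prog <- data.frame(
      id = paste0("ind", seq.int(nextId, length.out = tot)),
      sire = rep(mate, litters), dam = rep(dams, litters),
      sex = ifelse(runif(tot) < 0.5, "male", "female"),
      generation = g, stringsAsFactors = FALSE)
    # guarantee both sexes exist so the next generation can be mated
    if (g < config$generations && length(unique(prog$sex)) == 1L)
      prog$sex[1L] <- setdiff(c("male", "female"), prog$sex[1L])
    ped <- rbind(ped, prog)
    nextId <- nextId + tot
  }
  rownames(ped) <- NULL
  validatePedigree(ped)
  ped
}

# invariants: founders parentless, non-founders have both parents from an
# earlier generation (which also rules out ancestry cycles)
validatePedigree <- function(ped) {
  need <- c("id", "sire", "dam", "sex", "generation")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
  if (!all(ped$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  founder <- ped$generation == 0L
  if (any(!is.na(ped$sire[founder])) || any(!is.na(ped$dam[founder])))
    stop("founders must not have parents")
  nonf <- !founder
  if (any(is.na(ped$sire[nonf])) || any(is.na(ped$dam[nonf])))
    stop("non-founders need both a sire and a dam")
  gen <- setNames(ped$generation, ped$id)
  for (col in c("sire", "dam")) {
    par <- ped[[col]][nonf]
    missing <- setdiff(par, ped$id)
    if (length(missing))
      stop("pedigree refers to missing individual(s): ",
           paste(missing, collapse = ", "))
    if (any(gen[par] >= ped$generation[nonf]))
      stop("parents must come from an earlier generation")
  }
  sx <- setNames(ped$sex, ped$id)
  if (any(sx[ped$sire[nonf]] != "male") || any(sx[ped$dam[nonf]] != "female"))
    stop("sires must be male and dams female")
  invisible(TRUE)
}
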