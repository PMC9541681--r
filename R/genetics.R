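# Sex-chromosome genetics for the two shredder drive systems.
#
# Genotypes are short strings throughout the user-facing API:
#   XY system: "XX", "XY", "XYd"            (Yd = driving-Y / X-shredder)
#   ZW system: "ZW", "ZdW", "ZZ", "ZZd", "ZdZd"  (Zd = Z-linked W-shredder)
# Internally populations store an integer code for speed.

GENOTYPES <- c("XX", "XY", "XYd", "ZW", "ZdW", "ZZ", "ZZd", "ZdZd")
FEMALE_CODES <- c(1L, 4L, 5L)           # XX, ZW, ZdW
MALE_CODES <- c(2L, 3L, 6L, 7L, 8L)     # XY, XYd, ZZ, ZZd, ZdZd
CARRIER_CODES <- c(3L, 5L, 7L, 8L)      # XYd, ZdW, ZZd, ZdZd
XY_CODES <- 1:3
ZW_CODES <- 4:8

genotype_code <- function(genotype) {
  code <- match(genotype, GENOTYPES)
  if (anyNA(code)) {
    stop("invalid genotype(s): ",
         paste(unique(genotype[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

genotype_label <- function(code) GENOTYPES[code]

#' Sex of a genotype
#'
#' XX is female and XY/XYd male in the XY system; ZW/ZdW are female and
#' ZZ/ZZd/ZdZd male in the ZW system.
#'
#' @param genotype character vector of genotype strings (e.g. `"XYd"`).
#' @return character vector, `"female"` or `"male"`.
#' @export
sex_of <- function(genotype) {
  code <- genotype_code(genotype)
  ifelse(code %in% FEMALE_CODES, "female", "male")
}

is_carrier <- function(code) code %in% CARRIER_CODES

# Probability that an active shredder's surviving gamete carries the drive.
# A heterozygous shredder makes Zd (or Yd) and W (or X) gametes in equal
# numbers; the targeted chromosome's gametes are destroyed with probability c
# and the survivors are renormalized (carrier fecundity is unaffected):
# P(drive gamete) = (1/2) / (1/2 + (1 - c)/2) = 1 / (2 - c).
shredder_drive_prob <- function(c) 1 / (2 - c)

#' Gamete distribution of a genotype
#'
#' Mendelian segregation (1/2 each chromosome) for every genotype except the
#' two active shredders: an XYd male shreds X-bearing gametes and a ZdW female
#' shreds W-bearing gametes, each with efficiency `c`; survivors are
#' renormalized so total gametic output (and hence carrier fecundity) is
#' unchanged. At `c = 1` the carriers produce only drive gametes.
#'
#' @param genotype a single genotype string.
#' @param c shredding efficiency in `[0, 1]`.
#' @return named numeric vector of gamete probabilities summing to 1.
#' @export
gamete_distribution <- function(genotype, c = 1) {
  stopifnot(length(genotype) == 1L, c >= 0, c <= 1)
  code <- genotype_code(genotype)
  p <- shredder_drive_prob(c)
  switch(genotype,
    XX   = c(X = 1),
    XY   = c(X = 0.5, Y = 0.5),
    XYd  = c(X = 1 - p, Yd = p),
    ZW   = c(Z = 0.5, W = 0.5),
    ZdW  = c(Zd = p, W = 1 - p),
    ZZ   = c(Z = 1),
    ZZd  = c(Z = 0.5, Zd = 0.5),
    ZdZd = c(Zd = 1)
  )
}

pair_to_genotype <- function(g1, g2) {
  key <- paste(sort(c(g1, g2)), collapse = "/")
  switch(key,
    "X/X" = "XX", "X/Y" = "XY", "X/Yd" = "XYd",
    "W/Z" = "ZW", "W/Zd" = "ZdW",
    "Z/Z" = "ZZ", "Z/Zd" = "ZZd", "Zd/Zd" = "ZdZd",
    stop("gametes ", g1, " and ", g2, " do not form a valid genotype",
         call. = FALSE)
  )
}

#' Offspring genotype from one mating
#'
#' Samples one gamete from each parent's [gamete_distribution()] and pairs
#' them. The mother must be female, the father male, and both from the same
#' sex-determination system.
#'
#' @param mother,father genotype strings.
#' @param c shredding efficiency.
#' @param n number of independent offspring to draw.
#' @return character vector of `n` offspring genotype strings.
#' @export
offspring_genotype <- function(mother, father, c = 1, n = 1L) {
  mc <- genotype_code(mother); fc <- genotype_code(father)
  if (!(mc %in% FEMALE_CODES)) stop("mother must be female", call. = FALSE)
  if (!(fc %in% MALE_CODES)) stop("father must be male", call. = FALSE)
  if ((mc %in% XY_CODES) != (fc %in% XY_CODES)) {
    stop("parents must share a sex-determination system", call. = FALSE)
  }
  gm <- gamete_distribution(mother, c)
  gf <- gamete_distribution(father, c)
  mg <- sample(names(gm), n, replace = TRUE, prob = gm)
  fg <- sample(names(gf), n, replace = TRUE, prob = gf)
  vapply(seq_len(n), function(i) pair_to_genotype(mg[i], fg[i]), character(1))
}

# Vectorized offspring codes for the simulator. mother_code/father_code are
# per-offspring integer code vectors; returns offspring codes. One runif draw
# per gamete keeps everything reproducible under set.seed().
offspring_codes <- function(mother_code, father_code, c) {
  n <- length(mother_code)
  if (n == 0L) return(integer(0))
  p <- shredder_drive_prob(c)
  if (all(mother_code %in% XY_CODES)) {
    # maternal gamete is always X; offspring set by the paternal gamete
    u <- runif(n)
    out <- integer(n)
    xy <- father_code == 2L
    out[xy] <- ifelse(u[xy] < 0.5, 2L, 1L)              # Y -> XY, X -> XX
    xyd <- father_code == 3L
    out[xyd] <- ifelse(u[xyd] < p, 3L, 1L)              # Yd -> XYd, X -> XX
    return(out)
  }
  # ZW system: maternal gamete in {Z, Zd, W}; paternal in {Z, Zd}
  um <- runif(n)
  mat <- character(n)
  zw <- mother_code == 4L
  mat[zw] <- ifelse(um[zw] < 0.5, "Z", "W")
  zdw <- mother_code == 5L
  mat[zdw] <- ifelse(um[zdw] < p, "Zd", "W")
  uf <- runif(n)
  pat_zd <- (father_code == 7L & uf < 0.5) | father_code == 8L
  out <- integer(n)
  w <- mat == "W"
  out[w & !pat_zd] <- 4L   # ZW
  out[w & pat_zd] <- 5L    # ZdW
  z <- mat == "Z"
  out[z & !pat_zd] <- 6L   # ZZ
  out[z & pat_zd] <- 7L    # ZZd
  zd <- mat == "Zd"
  out[zd & !pat_zd] <- 7L  # ZZd
  out[zd & pat_zd] <- 8L   # ZdZd
  out
}

#' Drive allele frequency of a population
#'
#' For the XY system the frequency is the share of drive-bearing Y
#' chromosomes, i.e. carriers among males. For the ZW system two weightings
#' are available: `"chromosome"` counts Zd among all Z-type chromosomes
#' (males carry two Z slots, females one); `"individual"` averages the
#' within-individual Zd fraction over individuals, which is the state
#' variable iterated by the deterministic W-shredder recursion (see
#' [next_drive_frequency()] and [panmictic_next_frequency()]). The two
#' weightings coincide for the XY system.
#'
#' @param population a population object (see [initialize_population()]) or a
#'   character vector of genotype strings.
#' @param weighting `"chromosome"` (default) or `"individual"`.
#' @return frequency in `[0, 1]`, or `NA_real_` when the population is empty
#'   or carries no counted chromosomes.
#' @export
drive_allele_frequency <- function(population,
                                   weighting = c("chromosome", "individual")) {
  weighting <- match.arg(weighting)
  code <- if (is.character(population)) genotype_code(population)
          else population$genotype
  if (length(code) == 0L) return(NA_real_)
  if (all(code %in% XY_CODES)) {
    males <- sum(code %in% c(2L, 3L))
    if (males == 0L) return(NA_real_)
    return(sum(code == 3L) / males)
  }
  if (weighting == "chromosome") {
    zd <- sum(code == 5L) + sum(code == 7L) + 2L * sum(code == 8L)
    ztype <- sum(code %in% c(4L, 5L)) + 2L * sum(code %in% c(6L, 7L, 8L))
    if (ztype == 0L) return(NA_real_)
    zd / ztype
  } else {
    frac <- c(`4` = 0, `5` = 1, `6` = 0, `7` = 0.5, `8` = 1)
    mean(frac[as.character(code)])
  }
}

#' One-generation panmictic expectation of the drive frequency
#'
#' The mechanistic counterpart of the deterministic recursions, computed as an
#' exact expectation over mating classes using [gamete_distribution()] rather
#' than by sampling. The well-mixed population is constructed at drive
#' frequency `q`: for the X-shredder, a fraction `q` of males are XYd; for the
#' W-shredder, a fraction `q` of females are ZdW and male Z chromosomes carry
#' the drive at Hardy-Weinberg frequency `q`. Every female is mated to a
#' uniformly chosen male and all females have equal expected broods. The
#' returned value is the offspring drive frequency (individual weighting for
#' the ZW system, see [drive_allele_frequency()]).
#'
#' @param q parental drive frequency in `[0, 1]`.
#' @param c shredding efficiency.
#' @param system `"X_SHREDDER"` or `"W_SHREDDER"`.
#' @return expected offspring drive frequency.
#' @export
panmictic_next_frequency <- function(q, c,
                                     system = c("X_SHREDDER", "W_SHREDDER")) {
  system <- match.arg(system)
  stopifnot(all(q >= 0 & q <= 1), all(c >= 0 & c <= 1))
  if (length(c) > 1L || (length(q) > 1L && length(c) > 1L)) {
    return(mapply(panmictic_next_frequency, q = q, c = c,
                  MoreArgs = list(system = system)))
  }
  if (system == "X_SHREDDER") {
    # paternal Y-type gametes decide male offspring; mothers contribute X
    yd_from_xyd <- gamete_distribution("XYd", c)["Yd"]
    y_from_xy <- gamete_distribution("XY", c)["Y"]
    yd <- q * yd_from_xyd
    y <- (1 - q) * y_from_xy
    unname(yd / (yd + y))
  } else {
    # maternal gamete pool at ZdW frequency q
    pZ <- (1 - q) * unname(gamete_distribution("ZW", c)["Z"])
    pZd <- q * unname(gamete_distribution("ZdW", c)["Zd"])
    pW <- 1 - pZ - pZd
    # paternal Zd gamete probability equals q under Hardy-Weinberg males;
    # maternal W -> daughter with one paternal Z slot, maternal Z-type -> son
    # with a maternal and a paternal Z slot
    daughter_mean <- q
    son_mean <- (pZd / (pZ + pZd) + q) / 2
    out <- pW * daughter_mean + (pZ + pZd) * son_mean
    out[q == 0] <- 0  # pZd/(pZ + pZd) is 0/0-free for q > 0; fix the limit
    out
  }
}
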