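# The fixed-step Euler engine.
#
# Update rule: synchronous (Jacobi). Every flux of a step is evaluated from
# the state at the start of the step, then all fluxes are applied together.
# This makes the result independent of equation ordering and automatically
# excludes newborn cells from decay. Two capping rules guard against Euler
# overshoot: (i) a phage's total adsorption demand plus its decay/washout is
# capped at the free pool before any bacterial bookkeeping; (ii) the total
# outflux from each bacterial compartment is capped at its start-of-step
# content, scaling all of its outfluxes proportionally. Cohorts due to lyse
# in the current step lyse in full and are excluded from that step's
# pro-rata decay/washout/superinfection of the pending ledger.

# Precompute step-size-normalised rates and the addition schedule.
.precompute <- function(config) {
  b <- config$bacteria; ch <- config$chemostat
  pA <- config$phage_A; pB <- config$phage_B
  step <- config$step_size
  dt_h <- step / 3600
  dt_min <- step / 60
  spm <- as.integer(60 / step)
  n_steps <- as.integer(round(config$duration * 3600 / step))
  LAs <- max(1L, as.integer(round(pA$latent * 60 / step)))
  LBs <- max(1L, as.integer(round(pB$latent * 60 / step)))
  sched <- function(p) {
    add <- numeric(max(n_steps, 1L))
    init <- 0
    if (nrow(p$additions)) {
      for (r in seq_len(nrow(p$additions))) {
        k <- as.integer(round(p$additions[r, "time_h"] * 3600 / step))
        if (k <= 0L) init <- init + p$additions[r, "titre"]
        else if (k <= n_steps) add[k] <- add[k] + p$additions[r, "titre"]
      }
    }
    list(init = init, add = add)
  }
  sA <- sched(pA); sB <- sched(pB)
  list(dt_h = dt_h, dt_min = dt_min, spm = spm, n_steps = n_steps,
       K = b$K, eps = b$epsilon,
       gdtS = b$psi * dt_h, gdtRA = b$psi_RA * dt_h,
       gdtRB = b$psi_RB * dt_h, gdtRAB = b$psi_RAB * dt_h,
       muA = b$mu_A, muB = b$mu_B,
       muAB = double_resistance_rate(b$mu_A, b$mu_B),
       stochastic = config$mutation_mode == "Stochastic",
       gw = (b$gamma + ch$omega) * dt_h,
       gw_plank = (b$gamma + ch$omega) * dt_h,
       om_dt = ch$omega * dt_h,
       cin_dt = ch$C_in * ch$omega * dt_h,
       sig_dt = b$sigma * dt_min, rho_dt = b$rho * dt_min,
       in_small = 0.1 * dt_min,
       ref_on = config$refuge_mode != "Off",
       ref_lifo = config$refuge_mode == "LIFO",
       dA_dt = pA$delta * dt_min, dB_dt = pB$delta * dt_min,
       LAs = LAs, LBs = LBs, maxlat = max(LAs, LBs),
       betaA = pA$burst, betaB = pB$burst,
       pdecA = (pA$phi + ch$omega) * dt_h, pdecB = (pB$phi + ch$omega) * dt_h,
       susc = config$secondary_adsorption == "Susceptible",
       poisson = config$primary_adsorption == "Poisson",
       ref_adsorb = config$refuge_mode == "Planktonic" &&
         (config$primary_adsorption == "Poisson" ||
            config$secondary_adsorption == "Susceptible"),
       round1 = config$round_below_one,
       addA0 = sA$init, addA = sA$add, addB0 = sB$init, addB = sB$add)
}

#' Initialise a simulation state
#'
#' Builds the mutable state environment that [euler_step()] advances:
#' compartment titres, the nutrient concentration, free-phage pools,
#' cohort ledgers for the delayed-lysis compartments and (in LIFO refuge
#' mode) the refuge stacks. The starting population is split according to
#' the initial resistant frequencies; refuge compartments start empty;
#' phage additions scheduled at time 0 are included in the initial pools.
#'
#' @param config a validated [cocktail_config()].
#' @return an environment of class `cocktail_state`.
#' @seealso [euler_step()], [run_cocktail()]
#' @export
init_simulation_state <- function(config) {
  validate_config(config)
  pc <- .precompute(config)
  st <- new.env(parent = emptyenv())
  st$pc <- pc
  st$step <- 0L
  b <- config$bacteria
  f_tot <- b$f_RA + b$f_RB + b$f_RAB
  st$S <- b$S0 * (1 - f_tot)
  st$RA <- b$S0 * b$f_RA
  st$RB <- b$S0 * b$f_RB
  st$RAB <- b$S0 * b$f_RAB
  st$IA <- 0; st$IB <- 0; st$IABA <- 0; st$IABB <- 0
  st$RBIA <- 0; st$RAIB <- 0
  st$Sr <- 0; st$RrA <- 0; st$RrB <- 0; st$RrAB <- 0
  st$C <- config$chemostat$C0
  st$A <- pc$addA0
  st$B <- pc$addB0
  st$led <- new_cohort_ledger(pc$n_steps + pc$maxlat + 2L)
  if (pc$ref_lifo) {
    n <- pc$n_steps + 1L
    st$stk <- list(S_r = new_refuge_stack(n), R_rA = new_refuge_stack(n),
                   R_rB = new_refuge_stack(n), R_rAB = new_refuge_stack(n))
  } else {
    st$stk <- NULL
  }
  st$acc_PA <- 0; st$acc_PB <- 0; st$acc_relA <- 0; st$acc_relB <- 0
  class(st) <- c("cocktail_state", class(st))
  st
}

#' Advance the simulation state by one Euler step
#'
#' Evaluates every flux from the start-of-step state and applies them
#' together: lysis of due cohorts, Monod growth and nutrient consumption,
#' resistance mutation of the newborn cells, refuge exchange, decay,
#' adsorption and infection under the configured adsorption models,
#' superinfection routing by lysis-time competition, phage decay and
#' washout of all planktonic pools, scheduled phage additions, and (if
#' enabled) rounding of sub-unity pools. The state environment is modified
#' in place.
#'
#' @param st a state environment from [init_simulation_state()].
#' @return the state, invisibly.
#' @export
euler_step <- function(st) {
  pc <- st$pc
  j <- st$step + 1L
  led <- st$led

  C <- st$C; A <- st$A; B <- st$B
  S <- st$S; RA <- st$RA; RB <- st$RB; RAB <- st$RAB
  Sr <- st$Sr; RrA <- st$RrA; RrB <- st$RrB; RrAB <- st$RrAB

  ## --- lysis of cohorts due this step -------------------------------------
  rel <- lysis_release(led, j, pc$betaA, pc$betaB)
  relA <- rel$phage_A; relB <- rel$phage_B
  # pending (post-lysis) infected masses; guard float dust at zero
  IA <- max(0, st$IA - rel$lysed[["I_A"]])
  IB <- max(0, st$IB - rel$lysed[["I_B"]])
  IABA <- max(0, st$IABA - rel$lysed[["I_AB_A"]])
  IABB <- max(0, st$IABB - rel$lysed[["I_AB_B"]])
  RBIA <- max(0, st$RBIA - rel$lysed[["R_BIA"]])
  RAIB <- max(0, st$RAIB - rel$lysed[["R_AIB"]])
  IABp <- IABA + IABB

  ## --- growth, consumption, nutrient --------------------------------------
  mon <- C / (pc$K + C)
  bS <- S * pc$gdtS * mon
  bRA <- RA * pc$gdtRA * mon
  bRB <- RB * pc$gdtRB * mon
  bRAB <- RAB * pc$gdtRAB * mon
  cons <- pc$eps * (bS + bRA + bRB + bRAB)
  cwash <- C * pc$om_dt
  cout <- cons + cwash
  if (cout > C && cout > 0) {
    f <- C / cout
    cons <- cons * f; cwash <- cwash * f
    bS <- bS * f; bRA <- bRA * f; bRB <- bRB * f; bRAB <- bRAB * f
  }
  Cn <- C - cons - cwash + pc$cin_dt

  ## --- mutation at division -----------------------------------------------
  if (pc$stochastic) {
    mSA <- if (bS > 0 && pc$muA > 0) mutant_count(bS, pc$muA, "Stochastic") else 0
    mSB <- if (bS > 0 && pc$muB > 0) mutant_count(bS, pc$muB, "Stochastic") else 0
    mSAB <- if (bS > 0 && pc$muAB > 0) mutant_count(bS, pc$muAB, "Stochastic") else 0
    mRA <- if (bRA > 0 && pc$muB > 0) mutant_count(bRA, pc$muB, "Stochastic") else 0
    mRB <- if (bRB > 0 && pc$muA > 0) mutant_count(bRB, pc$muA, "Stochastic") else 0
  } else {
    mSA <- bS * pc$muA; mSB <- bS * pc$muB; mSAB <- bS * pc$muAB
    mRA <- bRA * pc$muB; mRB <- bRB * pc$muA
  }
  mtot <- mSA + mSB + mSAB
  if (mtot > bS && mtot > 0) {
    f <- bS / mtot
    mSA <- mSA * f; mSB <- mSB * f; mSAB <- mSAB * f
  }

  ## --- refuge exchange -----------------------------------------------------
  if (pc$ref_on) {
    inS <- if (S > 10) pc$sig_dt * S else pc$in_small
    inRA <- if (RA > 10) pc$sig_dt * RA else pc$in_small
    inRB <- if (RB > 10) pc$sig_dt * RB else pc$in_small
    inRAB <- if (RAB > 10) pc$sig_dt * RAB else pc$in_small
    outSr <- pc$rho_dt * Sr; outRrA <- pc$rho_dt * RrA
    outRrB <- pc$rho_dt * RrB; outRrAB <- pc$rho_dt * RrAB
  } else {
    inS <- inRA <- inRB <- inRAB <- 0
    outSr <- outRrA <- outRrB <- outRrAB <- 0
  }

  ## --- adsorption ----------------------------------------------------------
  # per-cell infection/adsorption fractions aA, aB for this step
  refA_cells <- if (pc$ref_adsorb) Sr + RrB else 0
  refB_cells <- if (pc$ref_adsorb) Sr + RrA else 0
  if (pc$poisson) {
    MA <- S + IB + RB + (if (pc$susc) IA + IABp + RBIA else 0) + refA_cells
    MB <- S + IA + RA + (if (pc$susc) IB + IABp + RAIB else 0) + refB_cells
    PbA <- if (MA > 0) poisson_bound(A, MA, pc$dA_dt, 1) else 0
    PbB <- if (MB > 0) poisson_bound(B, MB, pc$dB_dt, 1) else 0
    # cap bound + decay at the free pool
    outAr <- PbA + pc$pdecA * A
    fAp <- if (outAr > A && outAr > 0) A / outAr else 1
    outBr <- PbB + pc$pdecB * B
    fBp <- if (outBr > B && outBr > 0) B / outBr else 1
    PbA <- PbA * fAp; PbB <- PbB * fBp
    decA <- pc$pdecA * A * fAp; decB <- pc$pdecB * B * fBp
    aA <- if (MA > 0) poisson_infected(PbA, MA) / MA else 0
    aB <- if (MB > 0) poisson_infected(PbB, MB) / MB else 0
    lossA <- PbA; lossB <- PbB
  } else {
    aA <- pc$dA_dt * A
    aB <- pc$dB_dt * B
    demandA <- aA * (S + IB + RB + (if (pc$susc) IA + IABp + RBIA else 0) +
                       refA_cells)
    demandB <- aB * (S + IA + RA + (if (pc$susc) IB + IABp + RAIB else 0) +
                       refB_cells)
    outAr <- demandA + pc$pdecA * A
    fAp <- if (outAr > A && outAr > 0) A / outAr else 1
    outBr <- demandB + pc$pdecB * B
    fBp <- if (outBr > B && outBr > 0) B / outBr else 1
    aA <- aA * fAp; aB <- aB * fBp
    decA <- pc$pdecA * A * fAp; decB <- pc$pdecB * B * fBp
    lossA <- NA_real_; lossB <- NA_real_  # filled in after bacterial caps
  }

  ## --- bacterial compartment caps ------------------------------------------
  gw <- pc$gw
  infS_A <- aA * S; infS_B <- aB * S
  outS <- infS_A + infS_B + inS + gw * S
  facS <- if (outS > S && outS > 0) S / outS else 1
  infRA_B <- aB * RA
  outRA <- infRA_B + inRA + gw * RA
  facRA <- if (outRA > RA && outRA > 0) RA / outRA else 1
  infRB_A <- aA * RB
  outRB <- infRB_A + inRB + gw * RB
  facRB <- if (outRB > RB && outRB > 0) RB / outRB else 1
  outRAB <- inRAB + gw * RAB
  facRAB <- if (outRAB > RAB && outRAB > 0) RAB / outRAB else 1
  # refuge compartments: planktonic refuges decay and wash out, LIFO do not
  gwr <- if (pc$ref_lifo) 0 else gw
  capr <- function(pool, outflow) {
    tot <- outflow + gwr * pool
    if (tot > pool && tot > 0) pool / tot else 1
  }
  facSr <- capr(Sr, outSr); facRrA <- capr(RrA, outRrA)
  facRrB <- capr(RrB, outRrB); facRrAB <- capr(RrAB, outRrAB)
  # infected pending pools: per-cell removal fractions
  frIA <- gw + aB          # superinfected by B
  facIA <- if (frIA > 1) 1 / frIA else 1
  frIB <- gw + aA
  facIB <- if (frIB > 1) 1 / frIB else 1
  frI <- min(gw, 1)        # doubly infected and resistant-infected: decay/washout only
  facRBIA <- if (gw > 1) 1 / gw else 1
  facRAIB <- facRBIA

  ## --- apply ledger operations ---------------------------------------------
  infS_A_act <- infS_A * facS
  infS_B_act <- infS_B * facS
  infRB_A_act <- infRB_A * facRB
  infRA_B_act <- infRA_B * facRA
  si_IABA_from_IA <- 0; si_IABB_from_IA <- 0
  si_IABA_from_IB <- 0; si_IABB_from_IB <- 0
  nsl <- led$n_slots
  wfull <- seq.int(j + 1L, min(j + pc$maxlat, nsl))
  # decay/washout of the doubly infected pending cohorts must precede the
  # superinfection routing below, which adds fresh (undecayed) mass here
  if (IABA > 0 || IABB > 0) {
    led$I_AB_A[wfull] <- led$I_AB_A[wfull] * (1 - frI)
    led$I_AB_B[wfull] <- led$I_AB_B[wfull] * (1 - frI)
  }
  if (IA > 0) {
    w <- seq.int(j + 1L, min(j + pc$LAs, nsl))
    v <- led$I_A[w]
    sif <- aB * facIA
    siv <- v * sif
    led$I_A[w] <- v * (1 - sif - gw * facIA)
    if (sif > 0) {
      cut <- j + pc$LBs
      bwin <- w > cut            # superinfecting B lyses strictly earlier
      sB <- sum(siv[bwin])
      if (sB > 0) led$I_AB_B[cut] <- led$I_AB_B[cut] + sB
      if (any(!bwin)) {
        idx <- w[!bwin]
        led$I_AB_A[idx] <- led$I_AB_A[idx] + siv[!bwin]
      }
      si_IABB_from_IA <- sB
      si_IABA_from_IA <- sum(siv) - sB
    }
  }
  if (IB > 0) {
    w <- seq.int(j + 1L, min(j + pc$LBs, nsl))
    v <- led$I_B[w]
    sif <- aA * facIB
    siv <- v * sif
    led$I_B[w] <- v * (1 - sif - gw * facIB)
    if (sif > 0) {
      cut <- j + pc$LAs
      awin <- w > cut            # superinfecting A lyses strictly earlier
      sA <- sum(siv[awin])
      if (sA > 0) led$I_AB_A[cut] <- led$I_AB_A[cut] + sA
      if (any(!awin)) {
        idx <- w[!awin]
        led$I_AB_B[idx] <- led$I_AB_B[idx] + siv[!awin]
      }
      si_IABA_from_IB <- sA
      si_IABB_from_IB <- sum(siv) - sA
    }
  }
  if (RBIA > 0) {
    wA <- seq.int(j + 1L, min(j + pc$LAs, nsl))
    led$R_BIA[wA] <- led$R_BIA[wA] * (1 - gw * facRBIA)
  }
  if (RAIB > 0) {
    wB <- seq.int(j + 1L, min(j + pc$LBs, nsl))
    led$R_AIB[wB] <- led$R_AIB[wB] * (1 - gw * facRAIB)
  }
  if (infS_A_act > 0) ledger_add(led, "I_A", j + pc$LAs, infS_A_act)
  if (infS_B_act > 0) ledger_add(led, "I_B", j + pc$LBs, infS_B_act)
  if (infRB_A_act > 0) ledger_add(led, "R_BIA", j + pc$LAs, infRB_A_act)
  if (infRA_B_act > 0) ledger_add(led, "R_AIB", j + pc$LBs, infRA_B_act)

  ## --- phage pools ----------------------------------------------------------
  if (!pc$poisson) {
    # actual adsorption after bacterial caps; cells that stayed put (same-
    # phage secondary targets and refuge cells) still bind phage
    lossA <- infS_A_act + aA * IB * facIB + infRB_A_act +
      (if (pc$susc) aA * (IA + IABp + RBIA) else 0) + aA * refA_cells
    lossB <- infS_B_act + aB * IA * facIA + infRA_B_act +
      (if (pc$susc) aB * (IB + IABp + RAIB) else 0) + aB * refB_cells
  }
  An <- A + relA - lossA - decA + pc$addA[j]
  Bn <- B + relB - lossB - decB + pc$addB[j]

  ## --- bacterial scalars -----------------------------------------------------
  outSr_act <- outSr * facSr; outRrA_act <- outRrA * facRrA
  outRrB_act <- outRrB * facRrB; outRrAB_act <- outRrAB * facRrAB
  if (pc$ref_lifo && pc$ref_on) {
    outSr_act <- stack_withdraw(st$stk$S_r, outSr_act)
    outRrA_act <- stack_withdraw(st$stk$R_rA, outRrA_act)
    outRrB_act <- stack_withdraw(st$stk$R_rB, outRrB_act)
    outRrAB_act <- stack_withdraw(st$stk$R_rAB, outRrAB_act)
  }
  Sn <- S - outS * facS + bS - (mSA + mSB + mSAB) + outSr_act
  RAn <- RA - outRA * facRA + bRA + mSA - mRA + outRrA_act
  RBn <- RB - outRB * facRB + bRB + mSB - mRB + outRrB_act
  RABn <- RAB - outRAB * facRAB + bRAB + mSAB + mRA + mRB + outRrAB_act
  inS_act <- inS * facS; inRA_act <- inRA * facRA
  inRB_act <- inRB * facRB; inRAB_act <- inRAB * facRAB
  Srn <- Sr - (outSr + gwr * Sr) * facSr + inS_act
  RrAn <- RrA - (outRrA + gwr * RrA) * facRrA + inRA_act
  RrBn <- RrB - (outRrB + gwr * RrB) * facRrB + inRB_act
  RrABn <- RrAB - (outRrAB + gwr * RrAB) * facRrAB + inRAB_act
  if (pc$ref_lifo && pc$ref_on) {
    stack_push(st$stk$S_r, inS_act)
    stack_push(st$stk$R_rA, inRA_act)
    stack_push(st$stk$R_rB, inRB_act)
    stack_push(st$stk$R_rAB, inRAB_act)
  }
  # the ledgers are authoritative for the delayed compartments: the titres
  # are their pending sums. The closed-form updates below are recomputed as a
  # double-entry audit when checking is on.
  wIA <- seq.int(j + 1L, min(j + pc$LAs, nsl))
  wIB <- seq.int(j + 1L, min(j + pc$LBs, nsl))
  IAn <- sum(led$I_A[wIA])
  IBn <- sum(led$I_B[wIB])
  IABAn <- sum(led$I_AB_A[wfull])
  IABBn <- sum(led$I_AB_B[wfull])
  RBIAn <- sum(led$R_BIA[wIA])
  RAIBn <- sum(led$R_AIB[wIB])
  if (isTRUE(st$check)) {
    arith <- c(IA * (1 - (gw + aB) * facIA) + infS_A_act,
               IB * (1 - (gw + aA) * facIB) + infS_B_act,
               IABA * (1 - frI) + si_IABA_from_IA + si_IABA_from_IB,
               IABB * (1 - frI) + si_IABB_from_IA + si_IABB_from_IB,
               RBIA * (1 - gw * facRBIA) + infRB_A_act,
               RAIB * (1 - gw * facRAIB) + infRA_B_act)
    ledv <- c(IAn, IBn, IABAn, IABBn, RBIAn, RAIBn)
    tol <- 1e-9 * pmax(arith, ledv, 1)
    if (any(abs(arith - ledv) > tol)) {
      nm <- c("I_A", "I_B", "I_AB_A", "I_AB_B", "R_BIA", "R_AIB")
      bad <- which(abs(arith - ledv) > tol)[1]
      stop(sprintf("ledger mismatch for %s at step %d: flux arithmetic %.15g vs ledger sum %.15g",
                   nm[bad], j, arith[bad], ledv[bad]), call. = FALSE)
    }
  }

  ## --- rounding and write-back -----------------------------------------------
  if (pc$round1) {
    if (Sn > 0 && Sn < 1) Sn <- 0
    if (RAn > 0 && RAn < 1) RAn <- 0
    if (RBn > 0 && RBn < 1) RBn <- 0
    if (RABn > 0 && RABn < 1) RABn <- 0
    if (IAn > 0 && IAn < 1) { IAn <- 0; led$I_A[wfull] <- 0 }
    if (IBn > 0 && IBn < 1) { IBn <- 0; led$I_B[wfull] <- 0 }
    iab <- IABAn + IABBn
    if (iab > 0 && iab < 1) {
      IABAn <- 0; IABBn <- 0
      led$I_AB_A[wfull] <- 0; led$I_AB_B[wfull] <- 0
    }
    if (RBIAn > 0 && RBIAn < 1) { RBIAn <- 0; led$R_BIA[wfull] <- 0 }
    if (RAIBn > 0 && RAIBn < 1) { RAIBn <- 0; led$R_AIB[wfull] <- 0 }
    if (Srn > 0 && Srn < 1) {
      Srn <- 0
      if (pc$ref_lifo && pc$ref_on) stack_clear(st$stk$S_r)
    }
    if (RrAn > 0 && RrAn < 1) {
      RrAn <- 0
      if (pc$ref_lifo && pc$ref_on) stack_clear(st$stk$R_rA)
    }
    if (RrBn > 0 && RrBn < 1) {
      RrBn <- 0
      if (pc$ref_lifo && pc$ref_on) stack_clear(st$stk$R_rB)
    }
    if (RrABn > 0 && RrABn < 1) {
      RrABn <- 0
      if (pc$ref_lifo && pc$ref_on) stack_clear(st$stk$R_rAB)
    }
    if (An > 0 && An < 1) An <- 0
    if (Bn > 0 && Bn < 1) Bn <- 0
  }

  tot <- Cn + Sn + RAn + RBn + RABn + IAn + IBn + IABAn + IABBn +
    RBIAn + RAIBn + Srn + RrAn + RrBn + RrABn + An + Bn
  if (!is.finite(tot)) {
    stop(sprintf("numerical failure: non-finite state at step %d (t = %.4f h)",
                 j, j * pc$dt_h), call. = FALSE)
  }

  st$C <- Cn; st$A <- An; st$B <- Bn
  st$S <- Sn; st$RA <- RAn; st$RB <- RBn; st$RAB <- RABn
  st$IA <- IAn; st$IB <- IBn; st$IABA <- IABAn; st$IABB <- IABBn
  st$RBIA <- RBIAn; st$RAIB <- RAIBn
  st$Sr <- Srn; st$RrA <- RrAn; st$RrB <- RrBn; st$RrAB <- RrABn
  st$acc_PA <- st$acc_PA + lossA
  st$acc_PB <- st$acc_PB + lossB
  st$acc_relA <- st$acc_relA + relA
  st$acc_relB <- st$acc_relB + relB
  st$step <- j
  invisible(st)
}

# snapshot of the 16 recorded series, in canonical order
.state_row <- function(st) {
  c(st$S, st$IA, st$IB, st$IABA + st$IABB, st$RA, st$RB, st$RAB,
    st$RAIB, st$RBIA, st$Sr, st$RrA, st$RrB, st$RrAB, st$A, st$B, st$C)
}

#' Run a simulation
#'
#' Integrates the full system from time 0 to `config$duration` hours with
#' fixed Euler steps of `config$step_size` seconds, recording one row per
#' simulated minute (minute boundaries coincide with step boundaries for
#' all four step sizes). Scheduled phage additions are applied as impulses
#' at the nearest step boundary. In stochastic mutation mode the global RNG
#' is seeded from `config$seed` with the Mersenne-Twister generator and
#' Box-Muller normal sampling, and restored afterwards, so runs are
#' reproducible and side-effect free.
#'
#' @param config a [cocktail_config()] (validated again on entry).
#' @param diagnostics if `TRUE`, four extra columns are recorded: `P_A`,
#'   `P_B` (phage adsorbed since the previous record) and `rel_A`, `rel_B`
#'   (phage released by lysis since the previous record).
#' @param check if `TRUE`, verify after every step that each delayed
#'   compartment's titre equals the sum of its pending ledger cohorts to
#'   within 1e-9 relative (double-entry audit; slows the run down).
#' @return an object of class `cocktail_sim`: a list with `series` (a
#'   data.frame: `time_h`, the 13 bacterial titres, `A`, `B`, `C`, plus
#'   diagnostics if requested) and `config`.
#' @examples
#' sim <- run_cocktail(cocktail_config(duration = 2))
#' head(as.data.frame(sim))
#' @export
run_cocktail <- function(config, diagnostics = FALSE, check = FALSE) {
  validate_config(config)
  if (config$mutation_mode == "Stochastic") {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Box-Muller")
  }
  st <- init_simulation_state(config)
  st$check <- isTRUE(check)
  pc <- st$pc
  n_rec <- pc$n_steps %/% pc$spm + 1L
  ncol <- 17L + if (diagnostics) 4L else 0L
  rec <- matrix(0, nrow = n_rec, ncol = ncol)
  rec[1L, ] <- c(0, .state_row(st), if (diagnostics) numeric(4))
  r <- 1L
  if (pc$n_steps > 0L) {
    for (k in seq_len(pc$n_steps)) {
      euler_step(st)
      if (check) .audit_ledgers(st)
      if (k %% pc$spm == 0L) {
        r <- r + 1L
        rec[r, ] <- c(k * pc$dt_h, .state_row(st),
                      if (diagnostics) c(st$acc_PA, st$acc_PB,
                                         st$acc_relA, st$acc_relB))
        if (diagnostics) {
          st$acc_PA <- 0; st$acc_PB <- 0; st$acc_relA <- 0; st$acc_relB <- 0
        }
      }
    }
  }
  series <- as.data.frame(rec)
  names(series) <- c("time_h", cocktail_series_names(),
                     if (diagnostics) c("P_A", "P_B", "rel_A", "rel_B"))
  structure(list(series = series, config = config), class = "cocktail_sim")
}

# double-entry audit of the refuge stacks (the cohort-ledger audit runs
# inline in euler_step when st$check is set)
.audit_ledgers <- function(st) {
  pc <- st$pc
  if (pc$ref_lifo && pc$ref_on) {
    for (p in list(c("Sr", "S_r"), c("RrA", "R_rA"), c("RrB", "R_rB"),
                   c("RrAB", "R_rAB"))) {
      sc <- get(p[1], envir = st); tt <- st$stk[[p[2]]]$total
      if (abs(sc - tt) > 1e-9 * max(sc, tt, 1))
        stop(sprintf("refuge stack mismatch for %s at step %d", p[2], st$step),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
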