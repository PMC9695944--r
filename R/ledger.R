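# Infection-time cohort ledgers and refuge stacks.
#
# Delayed lysis is bookkept per cohort: cells infected during step k by a
# phage with a latent period of L steps form a cohort due to lyse during step
# k + L. Each infected compartment owns one ledger vector indexed by due
# step; doubly infected cells are split into two ledgers by the phage that
# will produce progeny (fixed at superinfection time by lysis-time
# competition), so exactly one phage type is released per cohort. Decay,
# washout and superinfection shrink pending cohorts pro rata, which keeps
# the ledger total equal to the compartment titre at every step.

# One ledger per delayed compartment. n_slots covers the whole run plus the
# longest latent period.
new_cohort_ledger <- function(n_slots) {
  led <- new.env(parent = emptyenv())
  for (nm in c("I_A", "I_B", "I_AB_A", "I_AB_B", "R_BIA", "R_AIB"))
    assign(nm, numeric(n_slots), envir = led)
  led$n_slots <- n_slots
  led
}

# Add an infection cohort (amount CFU/mL) due to lyse during `due`.
ledger_add <- function(ledger, compartment, due, amount) {
  v <- get(compartment, envir = ledger)
  v[due] <- v[due] + amount
  assign(compartment, v, envir = ledger)
  invisible(ledger)
}

# Sum of cohorts still pending after `step` (dues step+1 .. step+horizon).
ledger_pending <- function(ledger, compartment, step, horizon) {
  v <- get(compartment, envir = ledger)
  w <- seq.int(step + 1L, min(step + horizon, ledger$n_slots))
  sum(v[w])
}

#' Release phage from all cohorts due at a step
#'
#' Removes every infection cohort scheduled to lyse at `step` from the
#' ledger and converts the lysed cells to free phage at the producing
#' phage's burst size. Doubly infected cohorts carry the identity of the
#' winning (earlier-lysing) phage fixed at superinfection time, so each
#' cohort releases exactly one phage type. A burst size of zero removes the
#' cells without releasing anything (nonproductive infection).
#'
#' @param ledger a cohort ledger as found in the `led` field of the state
#'   environment returned by [init_simulation_state()].
#' @param step integer step index whose cohorts are due.
#' @param beta_A,beta_B burst sizes (PFU per lysed cell).
#' @return a list with `phage_A`, `phage_B` (PFU/mL released) and `lysed`, a
#'   named vector of lysed cells per infected compartment (CFU/mL).
#' @export
lysis_release <- function(ledger, step, beta_A, beta_B) {
  if (beta_A < 0 || beta_B < 0) stop("burst sizes must be nonnegative", call. = FALSE)
  take <- function(nm) {
    v <- get(nm, envir = ledger)
    a <- v[step]
    if (a != 0) { v[step] <- 0; assign(nm, v, envir = ledger) }
    a
  }
  ia <- take("I_A"); iaba <- take("I_AB_A"); rbia <- take("R_BIA")
  ib <- take("I_B"); iabb <- take("I_AB_B"); raib <- take("R_AIB")
  list(phage_A = beta_A * (ia + iaba + rbia),
       phage_B = beta_B * (ib + iabb + raib),
       lysed = c(I_A = ia, I_B = ib, I_AB = iaba + iabb,
                 I_AB_A = iaba, I_AB_B = iabb,
                 R_BIA = rbia, R_AIB = raib))
}

# --- LIFO refuge stacks ----------------------------------------------------

# Biofilm-like refuge: cohorts are pushed as cells enter and withdrawn
# newest-first when cells re-enter the planktonic pool. Amounts are indexed
# by push event; `top` is the newest occupied slot.
new_refuge_stack <- function(n_slots) {
  stk <- new.env(parent = emptyenv())
  stk$amt <- numeric(n_slots)
  stk$top <- 0L
  stk$total <- 0
  stk
}

stack_push <- function(stk, amount) {
  if (amount <= 0) return(invisible(stk))
  stk$top <- stk$top + 1L
  stk$amt[stk$top] <- amount
  stk$total <- stk$total + amount
  invisible(stk)
}

# Withdraw `amount`, consuming the most recently pushed cohorts first.
# Returns the amount actually withdrawn (bounded by the stack total).
stack_withdraw <- function(stk, amount) {
  want <- min(amount, stk$total)
  left <- want
  while (left > 0 && stk$top > 0L) {
    a <- stk$amt[stk$top]
    if (a <= left) {
      left <- left - a
      stk$amt[stk$top] <- 0
      stk$top <- stk$top - 1L
    } else {
      stk$amt[stk$top] <- a - left
      left <- 0
    }
  }
  stk$total <- stk$total - (want - left)
  want - left
}

stack_clear <- function(stk) {
  if (stk$top > 0L) stk$amt[seq_len(stk$top)] <- 0
  stk$top <- 0L
  stk$total <- 0
  invisible(stk)
}
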