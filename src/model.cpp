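// Fast right-hand side of the 21-state mitophagy ODE system, used by the
// integrator. Parameter order follows default_parameters(); species order
// follows mito_species(). The data-driven R implementation
// (reaction_rates/derivatives) is the reference; a test asserts agreement.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_mito_derivs(NumericVector y, NumericVector p) {
  double x[21];
  for (int i = 0; i < 21; ++i) x[i] = y[i] < 0 ? 0 : y[i];
  const double PINK1 = x[0], PINK1d = x[1], Parkin = x[2], ParkinpUb = x[3],
               pParkin = x[4], Ubpool = x[5], Ub = x[6], pUb = x[7],
               NDP52 = x[8], N_pUb = x[9], N_PE = x[10], N_pUb_PE = x[11],
               ULK1i = x[12], ULK1a = x[13], PtdIns = x[14], PI3P = x[15],
               Atg8 = x[16], Atg8PE = x[17], Stim = x[18], Atg4 = x[19],
               PPase = x[20];
  const double v1 = p[0];
  const double v2 = p[1] * PINK1;
  const double v3 = p[2] * PINK1d;
  const double v4 = p[3] * Stim * PINK1 * PINK1 - p[4] * PINK1d;
  const double v5 = p[5] * (pParkin + p[7]) * Ubpool / (p[6] + Ubpool);
  const double v6 = p[8] * PPase * Ub / (p[9] + Ub);
  const double v7 = p[10] * PINK1d * Ub / (p[11] + Ub);
  const double v8 = p[12] * PPase * pUb / (p[13] + pUb);
  const double v9 = p[14] * Parkin * pUb - p[15] * ParkinpUb;
  const double v10 = p[16] * PPase * pParkin / (p[17] + pParkin);
  const double v11 = p[18] * PINK1d * ParkinpUb / (p[19] + ParkinpUb);
  const double v12 = p[20] * NDP52 * pUb - p[21] * N_pUb;
  const double v13 = p[22] * N_pUb * Atg8PE - p[23] * N_pUb_PE;
  const double v14 = p[24] * (N_pUb + N_PE + N_pUb_PE + p[26]) * ULK1i /
                     (p[25] + ULK1i);
  const double v15 = p[27] * PPase * ULK1a / (p[28] + ULK1a);
  const double v16 = p[29] * ULK1a * PtdIns / (p[30] + PtdIns);
  const double v17 = p[31] * PPase * PI3P / (p[32] + PI3P);
  const double v18 = p[33] * PI3P * Atg8 / (p[34] + Atg8);
  const double v19 = p[35] * Atg4 * Atg8PE / (p[36] + Atg8PE);
  const double v20 = p[37] * NDP52 * Atg8PE - p[38] * N_PE;
  const double v21 = p[39] * N_PE * pUb - p[40] * N_pUb_PE;

  NumericVector dy(21);
  dy[0] = v1 - v2 - 2 * v4;          // PINK1
  dy[1] = v4 - v3;                   // PINK1d
  dy[2] = -v9 + v10;                 // Parkin
  dy[3] = v9 - v11;                  // Parkin_pUb
  dy[4] = v11 - v10;                 // pParkin
  dy[5] = -v5 + v6;                  // Ub_pool
  dy[6] = v5 - v6 - v7 + v8;         // Ub
  dy[7] = v7 - v8 - v9 + v11 - v12 - v21; // pUb
  dy[8] = -v12 - v20;                // NDP52
  dy[9] = v12 - v13;                 // NDP52_pUb
  dy[10] = v20 - v21;                // NDP52_Atg8PE
  dy[11] = v13 + v21;                // NDP52_pUb_Atg8PE
  dy[12] = -v14 + v15;               // ULK1i
  dy[13] = v14 - v15;                // ULK1a
  dy[14] = -v16 + v17;               // PtdIns
  dy[15] = v16 - v17;                // PtdIns3P
  dy[16] = -v18 + v19;               // Atg8
  dy[17] = v18 - v19 - v13 - v20;    // Atg8PE
  dy[18] = 0;                        // Stim (input)
  dy[19] = 0;                        // Atg4 (constant enzyme)
  dy[20] = 0;                        // PPase (constant enzyme)
  return dy;
}
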