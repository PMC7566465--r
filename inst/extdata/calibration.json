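{
  "targets": [0.15183246, 0.04712042, 0.17277487, 0.02617801, 0.03664921, 0.06544503],
  "n_sim": 200000,
  "iterations": [
    {
      "iter": 1,
      "rates": [0.00354279, 0.00094652, 0.00318828, 0.012, 0.01, 0.1],
      "observed": [0.09724, 0.027595, 0.182235, 0.00224, 0.019085, 0.022975]
    },
    {
      "iter": 2,
      "rates": [0.00553178, 0.00161625, 0.00302277, 0.048, 0.01920315, 0.28485322],
      "observed": [0.141775, 0.043945, 0.15918, 0.01107, 0.04085, 0.049285]
    },
    {
      "iter": 3,
      "rates": [0.0059242, 0.00173304, 0.00328093, 0.11350899, 0.01722841, 0.37825355],
      "observed": [0.14762, 0.047675, 0.16533, 0.025575, 0.036205, 0.066945]
    },
    {
      "iter": 4,
      "rates": [0.00609326, 0.00171288, 0.00342867, 0.11618532, 0.01743979, 0.36977838],
      "observed": [0.148595, 0.046345, 0.172455, 0.025975, 0.036635, 0.06622]
    },
    {
      "iter": 5,
      "rates": [0.00622601, 0.00174154, 0.00343503, 0.11709338, 0.01744656, 0.36545085],
      "observed": [0.15323, 0.04646, 0.16901, 0.026415, 0.037465, 0.06693]
    },
    {
      "iter": 6,
      "rates": [0.00616923, 0.00176629, 0.00351155, 0.11604284, 0.01706666, 0.35734261],
      "observed": [0.14959, 0.04657, 0.17167, 0.02663, 0.03529, 0.06706]
    },
    {
      "iter": 7,
      "rates": [0.00626171, 0.00178717, 0.00353415, 0.11407325, 0.017724, 0.3487369],
      "observed": [0.15078, 0.046435, 0.172545, 0.02624, 0.0372, 0.066205]
    },
    {
      "iter": 8,
      "rates": [0.00630542, 0.00181355, 0.00353886, 0.11380376, 0.01746157, 0.34473371],
      "observed": [0.152395, 0.04783, 0.173335, 0.02623, 0.037005, 0.0678]
    },
    {
      "iter": 9,
      "rates": [0.00628214, 0.00178664, 0.00352743, 0.1135782, 0.01729369, 0.33275969],
      "observed": [0.151105, 0.04857, 0.17179, 0.02659, 0.036395, 0.06837]
    },
    {
      "iter": 10,
      "rates": [0.00631238, 0.00173332, 0.00354765, 0.1118184, 0.01741448, 0.31852371],
      "observed": [0.15178, 0.04617, 0.17272, 0.02577, 0.03763, 0.06487]
    },
    {
      "iter": 11,
      "rates": [0.00631457, 0.001769, 0.00354878, 0.1135888, 0.01696059, 0.3213472],
      "observed": [0.152085, 0.046135, 0.17436, 0.02645, 0.035885, 0.06608]
    },
    {
      "iter": 12,
      "rates": [0.00630408, 0.00180679, 0.00351651, 0.11242074, 0.01732179, 0.31825932],
      "observed": [0.15173, 0.04764, 0.172275, 0.026415, 0.03689, 0.06711]
    }
  ],
  "final_rates": [0.00630834, 0.00178708, 0.00352672, 0.11141213, 0.01720873, 0.31036343],
  "final_fractions": [0.15252, 0.047215, 0.17279, 0.026265, 0.036405, 0.06651]
}
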