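>FtsB_periplasmic_25-88_synthetic constructed stand-in, not the natural sequence
LAELKQALAELRQALAELNQALEELEQALDELEQALEELDQALAQLKQAVAQLKNAQAELKSAK
>FtsL_periplasmic_61-109_synthetic constructed stand-in, not the natural sequence
LQELKEALSELREALEDLEEALEELDSAGDHSKSELQALVEAQSAKQAE
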