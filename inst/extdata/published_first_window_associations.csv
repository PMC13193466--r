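mirna,accession,or,ci_low,ci_high,p,p_fdr_published
let-7b-5p,MIMAT0000063,0.87,0.81,0.93,1.26e-4,1.49e-2
let-7g-5p,MIMAT0000414,0.90,0.84,0.96,1.04e-3,4.38e-2
let-7i-5p,MIMAT0000415,0.82,0.74,0.90,7.94e-5,1.27e-2
miR-15b-5p,MIMAT0000417,0.87,0.80,0.94,3.29e-4,2.61e-2
miR-18a-5p,MIMAT0000072,0.90,0.84,0.96,9.02e-4,4.23e-2
miR-20a-5p+miR-20b-5p,MIMAT0000075,0.83,0.76,0.92,1.31e-4,1.49e-2
miR-22-3p,MIMAT0000077,0.86,0.78,0.94,1.03e-3,4.38e-2
miR-93-5p,MIMAT0000093,0.85,0.77,0.93,3.94e-4,2.61e-2
miR-106a-5p+miR-17-5p,MIMAT0000103,0.84,0.77,0.91,3.44e-5,1.21e-2
miR-106b-5p,MIMAT0000680,0.91,0.87,0.97,1.15e-3,4.61e-2
miR-155-5p,MIMAT0000646,1.14,1.06,1.22,2.15e-4,2.15e-2
miR-181a-5p,MIMAT0000256,0.89,0.84,0.95,3.87e-4,2.61e-2
miR-191-5p,MIMAT0000440,0.82,0.75,0.89,3.20e-6,2.55e-3
miR-199a-3p+miR-199b-3p,MIMAT0000232,0.82,0.75,0.91,6.06e-5,1.21e-2
miR-223-3p,MIMAT0000280,0.86,0.80,0.94,3.58e-4,2.61e-2
miR-340-5p,MIMAT0004692,0.88,0.82,0.95,6.62e-4,3.53e-2
miR-451a,MIMAT0001631,0.88,0.82,0.95,4.25e-4,2.61e-2
miR-493-3p,MIMAT0003161,1.12,1.05,1.19,6.63e-4,3.53e-2
miR-640,MIMAT0003310,1.14,1.07,1.21,4.88e-5,1.21e-2
miR-1976,MIMAT0009451,1.11,1.04,1.18,8.86e-4,4.23e-2
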