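symbol,atomic_number,electronegativity,hardness_ev,covalent_radius_a,mass,n_valence_electrons,principal_quantum_number
H,1,2.20,6.43,0.31,1.008,1,1
B,5,2.04,4.01,0.84,10.81,3,2
C,6,2.55,5.00,0.76,12.011,4,2
N,7,3.04,7.23,0.71,14.007,5,2
O,8,3.44,6.08,0.66,15.999,6,2
F,9,3.98,7.01,0.57,18.998,7,2
Si,14,1.90,3.38,1.11,28.085,4,3
P,15,2.19,4.88,1.07,30.974,5,3
S,16,2.58,4.14,1.05,32.06,6,3
Cl,17,3.16,4.68,1.02,35.45,7,3
Se,34,2.55,3.87,1.20,78.971,6,4
Br,35,2.96,4.22,1.20,79.904,7,4
I,53,2.66,3.69,1.39,126.904,7,5
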