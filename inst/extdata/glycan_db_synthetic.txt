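# Synthetic N-glycan structure database (generator-derived; not a
# curated biological glycome). One nested-parenthesis structure per
# line; codes H=Hex, N=HexNAc, F=Fuc, A=NeuAc, G=NeuGc.
(N(F)(N(H(H(H(H))(H(H)))(H(H)))))
(N(F)(N(H(H(H(H))(H)(H))(H))))
(N(F)(N(H(H(H(H))(H))(H(H)(H)(H)))))
(N(F)(N(H(H(H(H)))(H(H)))))
(N(F)(N(H(H(H(H)))(H(N(H))(N)))))
(N(F)(N(H(H(H(H)))(H(N)(N)))))
(N(F)(N(H(H(H(H)))(H))))
(N(F)(N(H(H(H))(H(H)))))
(N(F)(N(H(H(H))(H(N)))))
(N(F)(N(H(H(H))(H))))
(N(F)(N(H(H(N(H(A)))(N))(H(N)))))
(N(F)(N(H(H(N(H(A))))(H(N)))))
(N(F)(N(H(H(N(H))(N))(H(N(H)))(N))))
(N(F)(N(H(H(N(H))(N))(H(N)(N))(N))))
(N(F)(N(H(H(N(H))(N))(H(N)(N)))))
(N(F)(N(H(H(N(H)))(H(N)(N)))))
(N(F)(N(H(H(N(H)))(H(N))(N))))
(N(F)(N(H(H(N(H)))(H(N)))))
(N(F)(N(H(H(N))(H(N))(N))))
(N(F)(N(H(H(N))(H(N)))))
(N(N(H(H(H(H))(H(H))(H)(H)(H))(H))))
(N(N(H(H(H(H))(H(H)))(H(N(H(A)))))))
(N(N(H(H(H(H))(H(H)))(H(N(H))(N)))))
(N(N(H(H(H(H))(H(H)))(H(N(H))))))
(N(N(H(H(H(H))(H)(H)(H))(H(H(H))))))
(N(N(H(H(H(H))(H)(H))(H(H(H))(H)))))
(N(N(H(H(H(H))(H)(H))(H(H)))))
(N(N(H(H(H(H))(H))(H(H(H))(H)))))
(N(N(H(H(H(H))(H))(H(H)(H)(H)(H)))))
(N(N(H(H(H(H))(H))(H(H)(H)(H)))))
(N(N(H(H(H(H))(H))(H(H)))))
(N(N(H(H(H(H))(H))(H(N(H))(N(H))))))
(N(N(H(H(H(H))(H))(H(N(H))))))
(N(N(H(H(H(H))(H))(H))))
(N(N(H(H(H(H)))(H(H)))))
(N(N(H(H(H(H)))(H(N(H(A)))(N(H))))))
(N(N(H(H(H(H)))(H(N(H))(N)(N)))))
(N(N(H(H(H(H)))(H(N(H))(N)))))
(N(N(H(H(H(H)))(H(N(H))))))
(N(N(H(H(H(H)))(H(N))(N))))
(N(N(H(H(H(H)))(H(N)))))
(N(N(H(H(H(H)))(H))))
(N(N(H(H(H))(H(H)))))
(N(N(H(H(H))(H(N(H(A)))(N)))))
(N(N(H(H(H))(H(N(H))(N)))))
(N(N(H(H(H))(H(N(H))))))
(N(N(H(H(H))(H(N))(N))))
(N(N(H(H(H))(H(N)))))
(N(N(H(H(N(H(A)))(N(H(A))))(H(N)))))
(N(N(H(H(N(H(A)))(N(H)))(H(N(H))))))
(N(N(H(H(N(H(A)))(N(H)))(H(N)))))
(N(N(H(H(N(H(A)))(N))(H(N(H))))))
(N(N(H(H(N(H(A)))(N))(H(N)(N)))))
(N(N(H(H(N(H(A)))(N))(H(N)))))
(N(N(H(H(N(H(A))))(H(N(H(A)))))))
(N(N(H(H(N(H(A))))(H(N(H))(N))(N))))
(N(N(H(H(N(H(A))))(H(N(H))(N)))))
(N(N(H(H(N(H(A))))(H(N(H)))(N))))
(N(N(H(H(N(H(A))))(H(N(H))))))
(N(N(H(H(N(H(A))))(H(N)(N)(N)))))
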