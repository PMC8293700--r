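form,lemma
clinico,clinica
aborto,abortar
dores,dor
feridas,ferida
curativos,curativo
medicacao,medicar
sangramento,sangrar
evolucoes,evolucao
pessoas,pessoa
cuidados,cuidado
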