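>CHEY_ECOLI chemotaxis response regulator CheY, Escherichia coli (UniProt P0AE67); numbering includes the initiator Met
MADKELKFLVVDDFSTMRRIVRNLLKELGFNNVEEAEDGVDALNKLQAGGYGFVISDWNM
PNMDGLELLKTIRADGAMSALPVLMVTAEAKKENIIAAAQAGASGYVVKPFTAATLEEKL
NKIFEKLGM
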