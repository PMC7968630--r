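((P003:34.93113463,(P004:28.70857886,P007:28.70857886):6.222555775):46.57587938,(P001:45.7904466,((P002:15.38213249,P005:15.38213249):19.38379911,(P006:16.12963112,P008:16.12963112):18.63630048):11.024515):35.71656741);
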