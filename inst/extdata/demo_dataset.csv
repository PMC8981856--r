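id,Quantity of prickles,Petal colour,Geographic origin,Breeding period,Number of flowers by volume
rb01,Low,pink,France,<1700,12
rb02,Low,light pink,NW-France,1700-1799,9
rb03,Medium,red,Brittany,1800-1809,15
rb04,Medium,,France,<1700,
rb05,High,yellow,China,1840-1849,27
rb06,High,orange,Japan,1850-1859,24
rb07,Very high,yellow,China,1860-1869,
rb08,Very high,orange,,1840-1849,31
rb09,,white,USA,1910-1919,40
rb10,Medium,white,Canada,>1920,44
rb11,Low,purple,USA,1910-1919,38
rb12,,dark red,,,
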