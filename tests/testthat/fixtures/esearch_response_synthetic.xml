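<?xml version="1.0" encoding="UTF-8"?>
<eSearchResult>
  <Count>3</Count>
  <RetMax>3</RetMax>
  <RetStart>0</RetStart>
  <IdList>
    <Id>7000001</Id>
    <Id>7000002</Id>
    <Id>7000003</Id>
  </IdList>
</eSearchResult>
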