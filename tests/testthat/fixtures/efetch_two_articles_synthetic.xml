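<?xml version="1.0" encoding="UTF-8"?>
<pmc-articleset>
  <article>
    <front>
      <article-meta>
        <article-id pub-id-type="pmc">7000001</article-id>
        <title-group>
          <article-title>Efflux pumps in multidrug-resistant bacteria</article-title>
        </title-group>
        <abstract>
          <p>Antibiotic efflux is a major resistance mechanism.</p>
        </abstract>
      </article-meta>
    </front>
    <body>
      <sec>
        <p>Efflux pumps export antibiotics from the cell.</p>
        <p>Overexpression confers multidrug resistance.</p>
      </sec>
    </body>
  </article>
  <article>
    <front>
      <article-meta>
        <article-id pub-id-type="pmc">7000002</article-id>
        <title-group>
          <article-title>Beta-lactamase diversity in clinical isolates</article-title>
        </title-group>
        <abstract>
          <p>Beta-lactamases hydrolyse beta-lactam antibiotics.</p>
        </abstract>
      </article-meta>
    </front>
    <body>
      <sec>
        <p>Extended-spectrum enzymes were detected in most isolates.</p>
      </sec>
    </body>
  </article>
</pmc-articleset>
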